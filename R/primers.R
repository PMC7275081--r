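# Nearest-neighbor duplex parameters (SantaLucia 1998 unified set):
# dH kcal/mol, dS cal/(mol K), 5'->3' top-strand dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature of a primer
#'
#' Two-state nearest-neighbor model with the unified duplex parameter
#' set, terminal initiation terms, monovalent-salt entropy correction
#' (0.368 cal/(mol K) per phosphate times ln\[Na+\]) and the usual C/4
#' concentration term for non-self-complementary duplexes.
#'
#' @param seq primer sequence, 5'->3'
#' @param primer_nM primer concentration in nM (50, the common
#'   primer-design default)
#' @param na_mM monovalent cation concentration in mM
#' @return melting temperature in degrees C
#' @export
primer_tm <- function(seq, primer_nM = 50, na_mM = 50) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 2) stop("primer too short for nearest-neighbor Tm")
  bases <- strsplit(s, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("primer contains non-ACGT characters")
  pairs <- paste0(bases[-n], bases[-1])
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  for (term in c(bases[1], bases[n])) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds + (-2.8) }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_mM / 1000)
  r <- 1.987  # cal/(mol K)
  tm_k <- dh * 1000 / (ds + r * log(primer_nM * 1e-9 / 4))
  tm_k - 273.15
}

#' GC fraction of a sequence
#' @param seq character sequence
#' @return fraction in \[0,1\]
#' @export
gc_content <- function(seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  sum(bases %in% c("G", "C")) / length(bases)
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Design a breakpoint-spanning validation primer pair
#'
#' Deterministic exhaustive search over the junction sequence: the
#' forward primer lies entirely 5' of the junction and the reverse
#' primer entirely 3', so the product always contains the junction.
#' Admissible primers are 18-27 nt, 30-70% GC, nearest-neighbor Tm
#' within `tm_range`, pair Tm difference at most `max_tm_diff`, and the
#' product length within `product_range` (200-400 bp at defaults). Among
#' admissible pairs the best under the penalty
#' `|Tm_fwd - 60| + |Tm_rev - 60| + |product - 300| / 50`
#' is returned; ties break to the leftmost forward primer, then the
#' shortest product. No randomness is involved. A hook for delegating to
#' an external design engine can replace this function wholesale since
#' only the returned fields are consumed downstream.
#'
#' @param junction_seq character sequence around the breakpoint
#' @param junction_offset 0-based offset of the junction within
#'   `junction_seq`
#' @param product_range allowed product length range (bases)
#' @param primer_len allowed primer length range (nt)
#' @param tm_range allowed melting temperature range (degrees C)
#' @param gc_range allowed GC fraction range
#' @param max_tm_diff maximum |Tm_fwd - Tm_rev| (degrees C)
#' @return list of class `primer_pair`: `fwd`, `rev`, `product_len`,
#'   `tm_fwd`, `tm_rev`
#' @export
design_primers <- function(junction_seq, junction_offset,
                           product_range = c(200, 400),
                           primer_len = c(18, 27),
                           tm_range = c(57, 63),
                           gc_range = c(0.3, 0.7),
                           max_tm_diff = 3) {
  seq <- toupper(as.character(junction_seq))
  n <- nchar(seq)
  if (n < product_range[1])
    stop("junction sequence (", n, " nt) cannot reach the minimum ",
         "product length of ", product_range[1], " bp")
  if (junction_offset <= 0 || junction_offset >= n)
    stop("junction_offset must be interior to the sequence")
  cand <- function(lo, hi, make_seq) {
    # all substrings [s, s+L) with lo <= s, s+L <= hi
    out <- list()
    for (L in primer_len[1]:primer_len[2]) {
      if (hi - L < lo) next
      starts <- seq.int(lo, hi - L)
      seqs <- substring(seq, starts + 1L, starts + L)
      out[[length(out) + 1L]] <- data.frame(
        start = starts, end = starts + L, seq = seqs,
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    if (is.null(df)) return(NULL)
    df$primer <- vapply(df$seq, make_seq, character(1), USE.NAMES = FALSE)
    df$gc <- vapply(df$primer, gc_content, numeric(1), USE.NAMES = FALSE)
    df <- df[df$gc >= gc_range[1] & df$gc <= gc_range[2], , drop = FALSE]
    if (nrow(df) == 0) return(df)
    df$tm <- vapply(df$primer, primer_tm, numeric(1), USE.NAMES = FALSE)
    df[df$tm >= tm_range[1] & df$tm <= tm_range[2], , drop = FALSE]
  }
  fwd_lo <- max(0L, junction_offset - product_range[2])
  fwd <- cand(fwd_lo, junction_offset, identity)
  rev_hi <- min(n, junction_offset + product_range[2])
  rev <- cand(junction_offset, rev_hi, revcomp_chr)
  diag_msg <- function() {
    paste0("no admissible primer pair: ",
           if (is.null(fwd) || nrow(fwd) == 0)
             "no forward primer passes the GC/Tm constraints; "
           else paste0(nrow(fwd), " forward candidates; "),
           if (is.null(rev) || nrow(rev) == 0)
             "no reverse primer passes the GC/Tm constraints"
           else paste0(nrow(rev), " reverse candidates"),
           " (lengths ", primer_len[1], "-", primer_len[2],
           " nt, GC ", gc_range[1] * 100, "-", gc_range[2] * 100,
           "%, Tm ", tm_range[1], "-", tm_range[2], " C, product ",
           product_range[1], "-", product_range[2], " bp)")
  }
  if (is.null(fwd) || nrow(fwd) == 0 || is.null(rev) || nrow(rev) == 0)
    stop(diag_msg())
  # deterministic prefilter keeps the pairing tractable on long inputs
  keep_best <- function(df, k = 200) {
    df[order(abs(df$tm - 60), df$start, df$end), , drop = FALSE][
      seq_len(min(nrow(df), k)), , drop = FALSE]
  }
  fwd <- keep_best(fwd)
  rev <- keep_best(rev)
  ij <- expand.grid(i = seq_len(nrow(fwd)), j = seq_len(nrow(rev)))
  product <- rev$end[ij$j] - fwd$start[ij$i]
  tmdiff <- abs(fwd$tm[ij$i] - rev$tm[ij$j])
  ok <- product >= product_range[1] & product <= product_range[2] &
    tmdiff <= max_tm_diff
  if (!any(ok)) stop(diag_msg())
  ij <- ij[ok, , drop = FALSE]
  product <- product[ok]
  score <- abs(fwd$tm[ij$i] - 60) + abs(rev$tm[ij$j] - 60) +
    abs(product - 300) / 50
  ord <- order(score, fwd$start[ij$i], product)
  best <- ord[1]
  structure(list(
    fwd = fwd$primer[ij$i[best]], rev = rev$primer[ij$j[best]],
    product_len = as.integer(product[best]),
    tm_fwd = fwd$tm[ij$i[best]], tm_rev = rev$tm[ij$j[best]]),
    class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer pair: fwd %s (Tm %.1f C), rev %s (Tm %.1f C), product %d bp\n",
              x$fwd, x$tm_fwd, x$rev, x$tm_rev, x$product_len))
  invisible(x)
}
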