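#' Find SpCas9 PAM sites (NGG) in a sequence window
#'
#' Scans one strand for all 20-nt protospacers with an NGG PAM
#' immediately 3' on that strand. Minus-strand sites are searched on the
#' reverse complement and mapped back to plus-strand coordinates, where
#' they appear as `CCN` motifs. The blunt Cas9 cut is placed 3 bp 5' of
#' the PAM (between protospacer positions 17 and 18).
#'
#' @param seq character or [Biostrings::DNAString] window (>= 23 nt for
#'   any hit)
#' @param strand "+" or "-": the strand carrying protospacer+PAM
#' @return data.frame `protospacer` (20 nt, 5'->3' on the design strand),
#'   `pam_pos` (0-based plus-strand offset of the PAM trinucleotide
#'   start within the window), `cut_pos` (0-based junction offset of the
#'   blunt cut), `strand`
#' @export
find_pam_sites <- function(seq, strand = c("+", "-")) {
  strand <- match.arg(strand)
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  empty <- data.frame(protospacer = character(), pam_pos = integer(),
                      cut_pos = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (n < 23) return(empty)
  if (strand == "+") {
    hits <- gregexpr("(?=[ACGT]GG)", seq, perl = TRUE)[[1]]
    hits <- hits[hits >= 21]  # need 20 nt protospacer 5' of the PAM
    if (length(hits) == 0 || hits[1] == -1) return(empty)
    data.frame(
      protospacer = substring(seq, hits - 20L, hits - 1L),
      pam_pos = as.integer(hits - 1L),
      cut_pos = as.integer(hits - 1L - 3L),
      strand = "+", stringsAsFactors = FALSE)
  } else {
    hits <- gregexpr("(?=CC[ACGT])", seq, perl = TRUE)[[1]]
    hits <- hits[hits + 22L <= n]  # protospacer occupies [pam+3, pam+23)
    if (length(hits) == 0 || hits[1] == -1) return(empty)
    proto_plus <- substring(seq, hits + 3L, hits + 22L)
    proto <- vapply(proto_plus, function(p)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
      character(1), USE.NAMES = FALSE)
    data.frame(
      protospacer = proto,
      pam_pos = as.integer(hits - 1L),
      cut_pos = as.integer(hits - 1L + 6L),
      strand = "-", stringsAsFactors = FALSE)
  }
}

#' Design a strand-directed crRNA tiling for a breakpoint window
#'
#' The design strand encodes the assay's directionality mechanism: the
#' sequencing adapter ligates to the PAM-proximal side of the Cas9 cut,
#' so reads run from the cut into the PAM-proximal flank — genomic
#' downstream for a plus-strand guide, upstream for a minus-strand
#' guide. When the unknown fusion partner is the 3' partner, guides are
#' designed on the known gene's sense strand (reads toward its
#' transcript-downstream side, where the junction lies); when the
#' unknown partner is the 5' partner, on the antisense strand.
#'
#' Sequential guides are placed left to right so that adjacent cut sites
#' are at most `max_spacing` apart across the window: one guide per
#' `max_spacing` stride, choosing the leftmost valid PAM at or after
#' each stride start (e.g. an 18 kb window at the 6 kb default yields 3
#' sequential guides).
#'
#' @param genome [Biostrings::DNAStringSet] reference
#' @param gene `Gene` to target (the known fusion partner)
#' @param role_unknown "5p" or "3p": role of the unknown partner
#' @param window 0-based half-open genomic interval on the gene's
#'   chromosome spanning the possible breakpoint region
#' @param max_spacing maximum gap between adjacent cut sites (bases);
#'   default 6000, the scale of a typical read length
#' @return data.frame `gene`, `role_unknown`, `protospacer`, `pam_pos`,
#'   `cut_pos` (genomic, 0-based), `design_strand`,
#'   `expected_read_direction` ("upstream"/"downstream", genomic)
#' @export
design_guides <- function(genome, gene, role_unknown = c("3p", "5p"),
                          window, max_spacing = 6000) {
  role_unknown <- match.arg(role_unknown)
  stopifnot(inherits(gene, "Gene"), length(window) == 2,
            window[2] > window[1])
  design_strand <- if (role_unknown == "3p") gene$strand else
    c(`+` = "-", `-` = "+")[[gene$strand]]
  direction <- if (design_strand == "+") "downstream" else "upstream"
  wseq <- Biostrings::subseq(genome[[gene$chrom]], window[1] + 1L,
                             window[2])
  sites <- find_pam_sites(wseq, design_strand)
  sites$cut_genomic <- sites$cut_pos + window[1]
  # greedy left-to-right: each next cut within max_spacing of the
  # previous one, so consecutive gaps are bounded by construction
  chosen <- integer(0)
  cursor <- window[1]
  anchor <- window[1]  # gap is measured from here (previous cut)
  repeat {
    limit <- min(anchor + max_spacing, window[2])
    ok <- which(sites$cut_genomic >= cursor & sites$cut_genomic <= limit)
    if (length(ok) == 0)
      stop("no PAM with a cut site in [", cursor, ",", limit,
           "] on the ", design_strand, " strand of ", gene$chrom)
    chosen <- c(chosen, ok[1])  # leftmost valid PAM in the stride
    cut <- sites$cut_genomic[ok[1]]
    if (cut + max_spacing >= window[2]) break
    anchor <- cut
    cursor <- cut + 1L
  }
  g <- sites[chosen, , drop = FALSE]
  data.frame(gene = gene$name, role_unknown = role_unknown,
             protospacer = g$protospacer,
             pam_pos = g$pam_pos + window[1],
             cut_pos = g$cut_genomic,
             design_strand = design_strand,
             expected_read_direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}
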