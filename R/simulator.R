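#' Synthetic genome configuration
#'
#' Describes the chromosomes and gene placements of a synthetic genome
#' used to exercise the pipeline without external data. The default
#' places four multi-exon CDS-bearing genes on both strands of two
#' chromosomes, one non-coding gene, and leaves ample intergenic decoy
#' space.
#'
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param genes data.frame with columns `name`, `chrom`, `start`
#'   (0-based), `strand`, `n_exons`, `exon_len`, `intron_len`, `coding`
#' @param utr_len bases of terminal exon sequence excluded from the CDS
#'   at each transcript end
#' @return list of class `genome_config`
#' @export
genome_config <- function(
    chrom_lengths = c(chrA = 120000L, chrB = 120000L),
    genes = data.frame(
      name = c("GENEA", "GENEB", "GENEC", "GENED", "GENEN"),
      chrom = c("chrA", "chrA", "chrB", "chrB", "chrB"),
      start = c(10000L, 40000L, 10000L, 40000L, 80000L),
      strand = c("+", "-", "+", "-", "+"),
      n_exons = c(4L, 3L, 5L, 4L, 2L),
      exon_len = c(300L, 400L, 250L, 300L, 200L),
      intron_len = c(1500L, 2000L, 1200L, 1500L, 800L),
      coding = c(TRUE, TRUE, TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    utr_len = 30L) {
  structure(list(chrom_lengths = chrom_lengths, genes = genes,
                 utr_len = utr_len), class = "genome_config")
}

#' Build a synthetic genome fixture (FASTA + GTF)
#'
#' Deterministic for a given seed: random-composition chromosome
#' sequences with the configured gene placements. Each gene gets one
#' transcript; exons are evenly spaced, and coding genes carry a CDS
#' covering the exons minus terminal UTRs. Writes a FASTA and a GTF
#' (1-based inclusive, as the format requires) and returns the in-memory
#' genome alongside.
#'
#' @param config a [genome_config()]
#' @param seed integer seed fixing every random draw
#' @param dir output directory (created if needed)
#' @return list with `genome` ([Biostrings::DNAStringSet]), `fasta`,
#'   `gtf` (paths), and `config`
#' @export
build_genome <- function(config = genome_config(), seed = 1,
                         dir = tempfile("genome")) {
  stopifnot(inherits(config, "genome_config"))
  g <- config$genes
  # reject overlapping gene placements per chromosome
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, , drop = FALSE]
    span <- gc$n_exons * gc$exon_len + (gc$n_exons - 1L) * gc$intron_len
    o <- order(gc$start)
    starts <- gc$start[o]; ends <- gc$start[o] + span[o]
    if (ch %in% names(config$chrom_lengths) &&
        any(ends > config$chrom_lengths[[ch]]))
      stop("gene extends past end of ", ch)
    if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
      stop("overlapping gene placements on ", ch)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- withr::with_seed(seed, {
    lapply(config$chrom_lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""))
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(config$chrom_lengths)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta)

  gtf_rows <- character(0)
  attr_str <- function(gid, tid = NULL) {
    paste0("gene_id \"", gid, "\"; ",
           if (!is.null(tid)) paste0("transcript_id \"", tid, "\"; "),
           "gene_name \"", gid, "\";")
  }
  for (i in seq_len(nrow(g))) {
    gn <- g[i, ]
    exon_starts <- gn$start + (seq_len(gn$n_exons) - 1L) *
      (gn$exon_len + gn$intron_len)
    exon_ends <- exon_starts + gn$exon_len
    gstart <- min(exon_starts); gend <- max(exon_ends)
    tid <- paste0(gn$name, ".t1")
    row <- function(type, s0, e0, tid_ = tid) {
      paste(gn$chrom, "longfuse_sim", type, s0 + 1L, e0, ".", gn$strand,
            ".", attr_str(gn$name, if (type == "gene") NULL else tid_),
            sep = "\t")
    }
    gtf_rows <- c(gtf_rows, row("gene", gstart, gend),
                  row("transcript", gstart, gend))
    for (e in seq_along(exon_starts))
      gtf_rows <- c(gtf_rows, row("exon", exon_starts[e], exon_ends[e]))
    if (isTRUE(gn$coding)) {
      cds_lo <- gstart + config$utr_len
      cds_hi <- gend - config$utr_len
      for (e in seq_along(exon_starts)) {
        s0 <- max(exon_starts[e], cds_lo)
        e0 <- min(exon_ends[e], cds_hi)
        if (e0 > s0) gtf_rows <- c(gtf_rows, row("CDS", s0, e0))
      }
    }
  }
  gtf <- file.path(dir, "genes.gtf")
  writeLines(gtf_rows, gtf)
  list(genome = genome, fasta = fasta, gtf = gtf, config = config)
}

adjacency_junctions <- function(map) {
  out <- list()
  for (i in seq_len(max(0L, nrow(map) - 1L))) {
    a <- map[i, ]; b <- map[i + 1L, ]
    colinear <- a$chrom == b$chrom &&
      ((a$strand == "+" && b$strand == "+" && a$end == b$start) ||
       (a$strand == "-" && b$strand == "-" && a$start == b$end))
    if (colinear) next
    e1 <- if (a$strand == "+") list(a$chrom, a$end, "L") else
      list(a$chrom, a$start, "R")
    e2 <- if (b$strand == "+") list(b$chrom, b$start, "R") else
      list(b$chrom, b$end, "L")
    if (e1[[1]] > e2[[1]] ||
        (e1[[1]] == e2[[1]] &&
         (e1[[2]] > e2[[2]] || (e1[[2]] == e2[[2]] && e1[[3]] > e2[[3]])))) {
      tmp <- e1; e1 <- e2; e2 <- tmp
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom1 = e1[[1]], pos1 = as.integer(e1[[2]]), side1 = e1[[3]],
      chrom2 = e2[[1]], pos2 = as.integer(e2[[2]]), side2 = e2[[3]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}


#' Apply a rearrangement to a reference genome
#'
#' Builds derivative haplotypes by literal sequence surgery from an
#' ordered list of operations, and enumerates the truth junctions each
#' operation creates (in the same retained-side encoding the breakend
#' caller uses):
#' \describe{
#'   \item{DEL}{`list(op="DEL", chrom=, start=, end=)` removes the
#'     0-based half-open interval; junction `(start,L)-(end,R)`.}
#'   \item{INV}{`list(op="INV", chrom=, start=, end=)`
#'     reverse-complements the interval in place; junctions
#'     `(start,L)-(end,L)` and `(start,R)-(end,R)`.}
#'   \item{JOIN}{`list(op="JOIN", chrom1=, pos1=, side1=, chrom2=,
#'     pos2=, side2=, name=)` fuses the retained flanks of two
#'     chromosomes into a new derivative (side L retains the
#'     genomic-left flank, R the right); junction
#'     `(pos1,side1)-(pos2,side2)`. Flank coordinates refer to the
#'     reference; DEL/INV already applied to the source chromosome are
#'     carried into the derivative.}
#' }
#' DEL/INV intervals must fall within a still-colinear (plus-strand)
#' block of the chromosome's current state.
#'
#' Truth junctions are enumerated from the *observable adjacencies* of
#' the derivative segment maps (deduplicated across derivatives), so
#' operations that touch — e.g. a deletion immediately followed by an
#' inverted segment — yield the single merged junction a spanning read
#' would actually produce, with the same retained-side encoding as
#' [breakends_from_read()].
#'
#' @param genome [Biostrings::DNAStringSet] reference
#' @param ops list of operation lists, applied left to right
#' @return list with `derivatives` (named list; every chromosome's
#'   current state plus one entry per JOIN, each with `seq`
#'   ([Biostrings::DNAString]) and `map`, the ordered reference-segment
#'   table) and `junctions` (data.frame `chrom1,pos1,side1,chrom2,pos2,
#'   side2,svtype` in canonical end order)
#' @export
apply_rearrangement <- function(genome, ops = list()) {
  state <- lapply(names(genome), function(ch)
    data.frame(chrom = ch, start = 0L, end = length(genome[[ch]]),
               strand = "+", stringsAsFactors = FALSE))
  names(state) <- names(genome)
  joins <- list()
  seg_containing <- function(segs, chrom, start, end) {
    i <- which(segs$strand == "+" & start >= segs$start & end <= segs$end)
    if (length(i) != 1)
      stop("interval [", start, ",", end, ") on ", chrom,
           " does not fall in a single colinear block")
    i
  }
  split_seg <- function(segs, i, cuts) {
    # replace segment i by consecutive pieces at the given ref cut points
    s <- segs[i, ]
    bounds <- unique(sort(c(s$start, cuts, s$end)))
    pieces <- data.frame(chrom = s$chrom, start = bounds[-length(bounds)],
                         end = bounds[-1], strand = "+",
                         stringsAsFactors = FALSE)
    rbind(segs[seq_len(i - 1L), , drop = FALSE], pieces,
          segs[seq_len(nrow(segs)) > i, , drop = FALSE])
  }
  for (op in ops) {
    kind <- toupper(op$op)
    if (kind %in% c("DEL", "INV")) {
      ch <- op$chrom
      if (!ch %in% names(state)) stop("unknown chromosome ", ch)
      if (op$start < 0 || op$end > length(genome[[ch]]) ||
          op$start >= op$end)
        stop(kind, " interval out of bounds on ", ch)
      segs <- state[[ch]]
      i <- seg_containing(segs, ch, op$start, op$end)
      segs <- split_seg(segs, i, c(op$start, op$end))
      mid <- which(segs$start == op$start & segs$end == op$end)
      if (kind == "DEL") {
        segs <- segs[-mid, , drop = FALSE]
      } else {
        segs$strand[mid] <- "-"
      }
      state[[ch]] <- segs
    } else if (kind == "JOIN") {
      flank <- function(ch, pos, side) {
        segs <- state[[ch]]
        i <- which(segs$strand == "+" & pos >= segs$start &
                     pos <= segs$end)
        if (length(i) < 1)
          stop("JOIN position ", pos, " on ", ch,
               " not in a colinear block")
        i <- i[1]
        if (side == "L") {
          part <- segs[seq_len(i), , drop = FALSE]
          part$end[i] <- pos
        } else {
          part <- segs[seq.int(i, nrow(segs)), , drop = FALSE]
          part$start[1] <- pos
        }
        part[part$end > part$start, , drop = FALSE]
      }
      rc_part <- function(part) {
        part <- part[rev(seq_len(nrow(part))), , drop = FALSE]
        part$strand <- ifelse(part$strand == "+", "-", "+")
        part
      }
      a <- flank(op$chrom1, op$pos1, op$side1)
      if (op$side1 == "R") a <- rc_part(a)
      b <- flank(op$chrom2, op$pos2, op$side2)
      if (op$side2 == "L") b <- rc_part(b)
      der <- rbind(a, b)
      rownames(der) <- NULL
      name <- if (!is.null(op$name)) op$name else
        paste0("der", length(joins) + 1L)
      joins[[name]] <- der
    } else stop("unknown rearrangement op: ", op$op)
  }
  build <- function(map) {
    pieces <- lapply(seq_len(nrow(map)), function(i) {
      s <- Biostrings::subseq(genome[[map$chrom[i]]], map$start[i] + 1L,
                              map$end[i])
      if (map$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    })
    Biostrings::DNAString(paste(unlist(pieces), collapse = ""))
  }
  derivatives <- c(state, joins)
  derivatives <- lapply(derivatives, function(map) {
    rownames(map) <- NULL
    list(seq = build(map), map = map)
  })
  jdf <- do.call(rbind, lapply(derivatives, function(d)
    adjacency_junctions(d$map)))
  if (is.null(jdf)) {
    jdf <- data.frame(chrom1 = character(), pos1 = integer(),
                      side1 = character(), chrom2 = character(),
                      pos2 = integer(), side2 = character(),
                      stringsAsFactors = FALSE)
  } else {
    jdf <- unique(jdf)
    jdf <- jdf[order(jdf$chrom1, jdf$pos1, jdf$chrom2, jdf$pos2), ,
               drop = FALSE]
    rownames(jdf) <- NULL
  }
  jdf$svtype <- classify_svtype(jdf)
  list(derivatives = derivatives, junctions = jdf)
}

#' Read simulation configuration
#'
#' Defaults emulate the Cas9 enrichment assay's observed conditions:
#' lognormal read lengths with a 9.9 kb mean, 50 capture reads per guide
#' cut, 0.2x uniform background coverage, a 48 h run with exponential
#' read-time decay placing about 70% of reads in the first 12 h, no
#' sequencing errors and no amplification chimeras (both available for
#' robustness scenarios).
#'
#' @param read_len_mean mean read length (bases)
#' @param read_len_sdlog lognormal sigma (log scale)
#' @param capture_reads_per_cut reads starting at each guide cut
#' @param background_cov mean background coverage (x)
#' @param error_rate i.i.d. substitution rate per base
#' @param chimera_per_1000 chimeric artifact reads per 1000 reads
#'   (whole-genome-amplification-like junction noise)
#' @param run_hours sequencing run duration
#' @param time_rate exponential decay rate (per hour) of read start
#'   times, truncated at `run_hours`
#' @param jitter maximum read-start offset from the cut site (bases)
#' @return list of class `sim_config`
#' @export
sim_config <- function(read_len_mean = 9900, read_len_sdlog = 0.5,
                       capture_reads_per_cut = 50, background_cov = 0.2,
                       error_rate = 0, chimera_per_1000 = 0,
                       run_hours = 48, time_rate = 0.1, jitter = 5) {
  cfg <- list(read_len_mean = read_len_mean,
              read_len_sdlog = read_len_sdlog,
              capture_reads_per_cut = capture_reads_per_cut,
              background_cov = background_cov, error_rate = error_rate,
              chimera_per_1000 = chimera_per_1000, run_hours = run_hours,
              time_rate = time_rate, jitter = jitter)
  if (any(unlist(cfg) < 0)) stop("simulation rates must be >= 0")
  structure(cfg, class = "sim_config")
}

rlen <- function(n, cfg) {
  meanlog <- log(cfg$read_len_mean) - cfg$read_len_sdlog^2 / 2
  pmax(200L, as.integer(round(rlnorm(n, meanlog, cfg$read_len_sdlog))))
}

rtime <- function(n, cfg) {
  u <- runif(n)
  r <- cfg$time_rate
  if (r <= 0) return(u * cfg$run_hours)
  -log(1 - u * (1 - exp(-r * cfg$run_hours))) / r
}

# map a half-open interval on a haplotype to reference provenance pieces
map_interval <- function(map, a, b) {
  seg_len <- map$end - map$start
  h1 <- cumsum(seg_len)
  h0 <- h1 - seg_len
  out <- list()
  for (i in seq_len(nrow(map))) {
    lo <- max(a, h0[i]); hi <- min(b, h1[i])
    if (hi <= lo) next
    off0 <- lo - h0[i]; off1 <- hi - h0[i]
    if (map$strand[i] == "+") {
      rs <- map$start[i] + off0; re <- map$start[i] + off1
    } else {
      re <- map$end[i] - off0; rs <- map$end[i] - off1
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = map$chrom[i], ref_start = as.integer(rs),
      ref_end = as.integer(re), strand = map$strand[i],
      read_start = as.integer(lo - a), read_end = as.integer(hi - a),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

flip_provenance <- function(prov, read_len) {
  prov$strand <- ifelse(prov$strand == "+", "-", "+")
  rs <- read_len - prov$read_end
  re <- read_len - prov$read_start
  prov$read_start <- rs; prov$read_end <- re
  prov[rev(seq_len(nrow(prov))), , drop = FALSE]
}

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit)
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  paste(bases, collapse = "")
}

#' Simulate Cas9-enrichment nanopore reads with truth provenance
#'
#' Capture reads start within `jitter` bases of each guide cut site and
#' extend only in the guide-dictated direction along the haplotype, with
#' lognormal lengths (truncated at the haplotype end, which is not an
#' error). Background reads are uniform in position and strand over the
#' reference at the configured coverage. Optional chimeric reads join
#' two uniformly drawn loci. Every read gets a start time from a
#' truncated exponential over the run, and substitution errors at the
#' configured rate. All draws are fixed by the seed.
#'
#' @param genome reference [Biostrings::DNAStringSet] (background reads)
#' @param rearrangement result of [apply_rearrangement()], or `NULL` for
#'   a rearrangement-free run
#' @param cuts data.frame with columns `haplotype` (name of a derivative
#'   or chromosome), `pos` (0-based cut position in haplotype
#'   coordinates) and `direction` ("right" or "left": which side of the
#'   cut is sequenced)
#' @param config a [sim_config()]
#' @param seed integer seed
#' @return list of class `longfuse_sim`: `reads` (named character),
#'   `provenance` (per-read reference segments with read intervals and
#'   `is_chimera`), `times` (named hours), `junctions` (truth junction
#'   table), `config`, `seed`
#' @export
simulate_reads <- function(genome, rearrangement = NULL,
                           cuts = NULL, config = sim_config(), seed = 1) {
  haps <- if (!is.null(rearrangement)) rearrangement$derivatives else
    lapply(names(genome), function(ch)
      list(seq = genome[[ch]],
           map = data.frame(chrom = ch, start = 0L,
                            end = length(genome[[ch]]), strand = "+",
                            stringsAsFactors = FALSE)))
  if (is.null(names(haps)) && is.null(rearrangement))
    names(haps) <- names(genome)
  withr::with_seed(seed, {
    reads <- character(0)
    prov <- list()
    nread <- 0L
    new_read <- function(seq, pieces, chimera = FALSE) {
      nread <<- nread + 1L
      id <- sprintf("read%05d", nread)
      reads[[id]] <<- seq
      pieces$read_id <- id
      pieces$is_chimera <- chimera
      prov[[id]] <<- pieces
      id
    }
    if (!is.null(cuts)) for (ci in seq_len(nrow(cuts))) {
      cut <- cuts[ci, ]
      hap <- haps[[cut$haplotype]]
      if (is.null(hap)) stop("unknown haplotype ", cut$haplotype)
      hlen <- length(hap$seq)
      for (k in seq_len(config$capture_reads_per_cut)) {
        start <- cut$pos + sample(seq(-config$jitter, config$jitter), 1)
        start <- min(max(start, 0L), hlen)
        len <- rlen(1, config)
        if (cut$direction == "right") {
          a <- start; b <- min(start + len, hlen)
          if (b <= a) next
          seq <- as.character(Biostrings::subseq(hap$seq, a + 1L, b))
          pieces <- map_interval(hap$map, a, b)
        } else {
          a <- max(start - len, 0L); b <- start
          if (b <= a) next
          seq <- as.character(Biostrings::reverseComplement(
            Biostrings::subseq(hap$seq, a + 1L, b)))
          pieces <- flip_provenance(map_interval(hap$map, a, b), b - a)
        }
        new_read(seq, pieces)
      }
    }
    glens <- vapply(names(genome), function(ch)
      length(genome[[ch]]), integer(1))
    if (config$background_cov > 0) {
      n_bg <- max(0L, as.integer(round(
        config$background_cov * sum(glens) / config$read_len_mean)))
      for (k in seq_len(n_bg)) {
        ch <- sample(names(glens), 1, prob = glens / sum(glens))
        a <- sample.int(glens[[ch]], 1) - 1L
        b <- min(a + rlen(1, config), glens[[ch]])
        if (b <= a) next
        seq <- as.character(Biostrings::subseq(genome[[ch]], a + 1L, b))
        pieces <- data.frame(chrom = ch, ref_start = a, ref_end = b,
                             strand = "+", read_start = 0L,
                             read_end = b - a, stringsAsFactors = FALSE)
        if (runif(1) < 0.5) {
          seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
          pieces <- flip_provenance(pieces, b - a)
        }
        new_read(seq, pieces)
      }
    }
    if (config$chimera_per_1000 > 0) {
      n_ch <- as.integer(round(config$chimera_per_1000 / 1000 * nread))
      for (k in seq_len(n_ch)) {
        halves <- lapply(1:2, function(x) {
          ch <- sample(names(glens), 1, prob = glens / sum(glens))
          len <- max(500L, as.integer(rlen(1, config) / 2))
          a <- sample.int(max(1L, glens[[ch]] - len), 1) - 1L
          b <- min(a + len, glens[[ch]])
          list(chrom = ch, a = a, b = b,
               seq = as.character(Biostrings::subseq(genome[[ch]],
                                                     a + 1L, b)))
        })
        l1 <- halves[[1]]$b - halves[[1]]$a
        l2 <- halves[[2]]$b - halves[[2]]$a
        pieces <- data.frame(
          chrom = c(halves[[1]]$chrom, halves[[2]]$chrom),
          ref_start = c(halves[[1]]$a, halves[[2]]$a),
          ref_end = c(halves[[1]]$b, halves[[2]]$b),
          strand = "+", read_start = c(0L, l1),
          read_end = c(l1, l1 + l2), stringsAsFactors = FALSE)
        new_read(paste0(halves[[1]]$seq, halves[[2]]$seq), pieces,
                 chimera = TRUE)
      }
    }
    times <- rtime(nread, config)
    names(times) <- names(reads)
    # errors drawn last so coordinates are seed-identical across error
    # settings
    if (config$error_rate > 0)
      reads <- vapply(reads, apply_errors, character(1),
                      rate = config$error_rate)
    provenance <- do.call(rbind, prov)
    rownames(provenance) <- NULL
    structure(list(
      reads = unlist(reads),
      provenance = provenance,
      times = times,
      junctions = if (!is.null(rearrangement)) rearrangement$junctions
                  else NULL,
      config = config, seed = seed), class = "longfuse_sim")
  })
}

#' @export
print.longfuse_sim <- function(x, ...) {
  cat(sprintf("longfuse_sim: %d reads (mean length %.0f), %d truth junction(s), seed %d\n",
              length(x$reads), mean(nchar(x$reads)),
              if (is.null(x$junctions)) 0L else nrow(x$junctions),
              x$seed))
  invisible(x)
}

#' Write simulated reads as FASTQ
#' @param sim a `longfuse_sim`
#' @param path output FASTQ path
#' @return `path`, invisibly
#' @export
write_fastq <- function(sim, path) {
  ids <- names(sim$reads)
  qual <- vapply(nchar(sim$reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", ids), unname(sim$reads), "+",
                           unname(qual)))
  writeLines(lines, path)
  invisible(path)
}

#' Write truth alignments of simulated reads as SAM
#'
#' Emits one primary plus supplementary records per read with exact
#' CIGARs (soft clips and a single match block per provenance segment),
#' SA tags linking the segments, MAPQ 60, and the read's sequencing
#' start time in an `st:f` tag. In error-free mode (and with the
#' substitution-only error model generally) coordinates are base-exact,
#' standing in for an aligner in hermetic tests; externally aligned SAM
#' is equally accepted by [read_alignments()].
#'
#' @param sim a `longfuse_sim`
#' @param genome the reference [Biostrings::DNAStringSet] (for `@SQ`
#'   header lines)
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_truth_sam <- function(sim, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   vapply(names(genome), function(ch)
                     length(genome[[ch]]), integer(1))))
  recs <- character(0)
  for (id in names(sim$reads)) {
    seq <- sim$reads[[id]]
    read_len <- nchar(seq)
    segs <- sim$provenance[sim$provenance$read_id == id, , drop = FALSE]
    segs <- segs[order(segs$read_start), , drop = FALSE]
    if (any(segs$read_end - segs$read_start !=
              segs$ref_end - segs$ref_start))
      stop("provenance of ", id, " does not tile the read")
    aln_len <- segs$read_end - segs$read_start
    primary <- which.max(aln_len)
    sam_cigar <- function(i) {
      lclip <- if (segs$strand[i] == "+") segs$read_start[i] else
        read_len - segs$read_end[i]
      rclip <- if (segs$strand[i] == "+") read_len - segs$read_end[i] else
        segs$read_start[i]
      paste0(if (lclip > 0) paste0(lclip, "S"), aln_len[i], "M",
             if (rclip > 0) paste0(rclip, "S"))
    }
    for (i in seq_len(nrow(segs))) {
      flag <- 0L
      if (segs$strand[i] == "-") flag <- flag + 16L
      if (i != primary) flag <- flag + 2048L
      oseq <- if (segs$strand[i] == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seq))) else seq
      tags <- sprintf("st:f:%.4f", sim$times[[id]])
      if (nrow(segs) > 1) {
        others <- setdiff(seq_len(nrow(segs)), i)
        sa <- paste(vapply(others, function(j)
          paste0(segs$chrom[j], ",", segs$ref_start[j] + 1L, ",",
                 segs$strand[j], ",", sam_cigar(j), ",60,0;"),
          character(1)), collapse = "")
        tags <- paste0("SA:Z:", sa, "\t", tags)
      }
      recs <- c(recs, paste(id, flag, segs$chrom[i],
                            segs$ref_start[i] + 1L, 60, sam_cigar(i),
                            "*", 0, 0, oseq, "*", tags, sep = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
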