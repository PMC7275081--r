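#' Mean read depth over a genomic region
#'
#' Mean per-base depth contributed by aligned segments over the 0-based
#' half-open region, i.e. total overlapped bases divided by region
#' length.
#'
#' @param segments data.frame from [read_alignments()]
#' @param chrom chromosome
#' @param start,end 0-based half-open region bounds; `end > start`
#' @return mean depth (x)
#' @export
region_coverage <- function(segments, chrom, start, end) {
  if (end <= start) stop("empty region: [", start, ",", end, ")")
  s <- segments[segments$chrom == chrom, , drop = FALSE]
  if (nrow(s) == 0) return(0)
  ov <- pmax(0, pmin(s$ref_end, end) - pmax(s$ref_start, start))
  sum(ov) / (end - start)
}

#' Mean genome-wide coverage
#'
#' Total aligned bases (on- and off-target) divided by genome length.
#'
#' @param segments data.frame from [read_alignments()]
#' @param genome_length total genome length in bases
#' @return mean depth (x)
#' @export
genome_coverage <- function(segments, genome_length) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  sum(segments$ref_end - segments$ref_start) / genome_length
}

#' Fold enrichment of a target signal over genome coverage
#'
#' @param target target-region depth (x) or junction-crossing read count
#' @param genome_cov mean genome coverage (x); must be > 0
#' @return `target / genome_cov`
#' @export
fold_enrichment <- function(target, genome_cov) {
  if (any(genome_cov <= 0)) stop("genome coverage must be > 0")
  target / genome_cov
}

#' Reads spanning a breakpoint position
#'
#' Counts distinct reads whose alignment covers the base immediately
#' left of the junction coordinate, i.e. the depth at the breakpoint
#' base. This includes both reads whose single segment continues across
#' the position on the reference and split reads clipped exactly at the
#' junction (which continue on the fusion partner), so fusion-spanning
#' reads are always a subset of breakpoint-spanning reads.
#'
#' @param segments data.frame from [read_alignments()]
#' @param chrom chromosome
#' @param pos 0-based junction coordinate
#' @return integer read count
#' @export
breakpoint_spanning_reads <- function(segments, chrom, pos) {
  s <- segments[segments$chrom == chrom & segments$ref_start < pos &
                  segments$ref_end >= pos, , drop = FALSE]
  length(unique(s$read_id))
}

#' Fraction of cut-site reads sequenced in the expected direction
#'
#' A read "starts at the cut" when the genomic position of its outermost
#' read start (read base 0 of its first segment in read order) maps
#' within `window` bases of `cut_pos`. A starter matches when its
#' alignment extends from the cut in the expected genomic direction
#' ("downstream" = increasing coordinates, i.e. a '+' first segment;
#' "upstream" = decreasing, '-'). Returns matches / starters, or `NA`
#' when no read starts at the cut.
#'
#' @param segments data.frame from [read_alignments()]
#' @param chrom chromosome of the cut site
#' @param cut_pos 0-based cut position
#' @param expected_direction "downstream" or "upstream"
#' @param window half-width (bases) of the start-at-cut window
#' @return fraction in \[0,1\], or `NA_real_`
#' @export
read_directionality <- function(segments, chrom, cut_pos,
                                expected_direction = c("downstream", "upstream"),
                                window = 50) {
  expected_direction <- match.arg(expected_direction)
  firsts <- do.call(rbind, lapply(split(segments, segments$read_id),
    function(s) s[which.min(s$read_start), , drop = FALSE]))
  if (is.null(firsts)) return(NA_real_)
  start_pos <- ifelse(firsts$strand == "+", firsts$ref_start,
                      firsts$ref_end)
  starter <- firsts$chrom == chrom & abs(start_pos - cut_pos) <= window
  if (!any(starter)) return(NA_real_)
  dir <- ifelse(firsts$strand == "+", "downstream", "upstream")
  sum(starter & dir == expected_direction) / sum(starter)
}

#' Cumulative fusion-spanning reads over sequencing time bins
#'
#' Run start `t0` is the earliest read's timestamp over all reads (not
#' just fusion reads). Per bin, reports the cumulative number of
#' fusion-spanning reads sequenced within the bin's hours after `t0` and
#' the percentage of the final total. The earliest bin reaching at least
#' `min_reads` fusion reads is returned as attribute
#' `"time_to_threshold"` (in hours; `NA` when never reached).
#'
#' @param start_times numeric hours for every read
#' @param is_fusion logical, same length: is the read fusion-spanning?
#' @param bins cumulative bin ends in hours after the first read
#' @param min_reads detection threshold in fusion-spanning reads
#' @return data.frame `bin_h`, `cumulative_reads`, `pct_of_final`, with
#'   attribute `time_to_threshold`
#' @export
timecourse <- function(start_times, is_fusion,
                       bins = c(1, 2, 3, 4, 5, 6, 12, 18, 24, 30, 36, 42, 48),
                       min_reads = 2) {
  if (length(start_times) == 0 || all(is.na(start_times)))
    stop("no read timestamps available")
  stopifnot(length(start_times) == length(is_fusion))
  t0 <- min(start_times, na.rm = TRUE)
  rel <- start_times[is_fusion] - t0
  cum <- vapply(bins, function(b) sum(rel <= b), integer(1))
  total <- length(rel)
  res <- data.frame(
    bin_h = bins, cumulative_reads = cum,
    pct_of_final = if (total > 0) 100 * cum / total else rep(NA_real_, length(bins)))
  reached <- which(cum >= min_reads)
  attr(res, "time_to_threshold") <-
    if (length(reached) > 0) bins[min(reached)] else NA_real_
  res
}

#' Fusion counts across supporting-read thresholds
#'
#' Counts fusions retained at minimum support 1, 2, 3, 4 and 5+ from
#' calls made at minimum support 1. The vector is nonincreasing in the
#' threshold.
#'
#' @param support integer vector of per-fusion distinct supporting read
#'   counts (from a run at min_support = 1)
#' @param thresholds thresholds to sweep
#' @return named integer vector of counts
#' @export
cutoff_sweep <- function(support, thresholds = 1:5) {
  counts <- vapply(thresholds, function(t) sum(support >= t), integer(1))
  names(counts) <- ifelse(thresholds == max(thresholds) &
                            thresholds == 5, "5+", as.character(thresholds))
  counts
}

#' Per-target enrichment report
#'
#' Assembles the assay's readout triad for one targeted locus: mean
#' genome coverage, on-target coverage (cut-to-breakpoint region), reads
#' crossing the breakpoint, fusion-spanning reads, and the corresponding
#' fold enrichments over genome coverage (breakpoint and fusion signals
#' are junction-crossing read counts, i.e. depth at the junction).
#'
#' @param segments data.frame from [read_alignments()]
#' @param genome_length total genome length
#' @param chrom targeted chromosome
#' @param cut_pos 0-based guide cut position
#' @param breakpoint_pos 0-based breakpoint position
#' @param fusion_spanning number of fusion-spanning reads at this
#'   junction (from the SV call support)
#' @param expected_direction expected read direction from the cut
#' @return one-row data.frame: `genome_cov`, `ontarget_cov`,
#'   `bp_spanning`, `fusion_spanning`, `fold_ontarget`, `fold_bp`,
#'   `fold_fusion`, `directionality`
#' @export
enrichment_report <- function(segments, genome_length, chrom, cut_pos,
                              breakpoint_pos, fusion_spanning,
                              expected_direction = c("downstream", "upstream")) {
  expected_direction <- match.arg(expected_direction)
  gcov <- genome_coverage(segments, genome_length)
  region <- sort(c(cut_pos, breakpoint_pos))
  if (region[2] == region[1]) region[2] <- region[1] + 1L
  ontarget <- region_coverage(segments, chrom, region[1], region[2])
  bp <- breakpoint_spanning_reads(segments, chrom, breakpoint_pos)
  data.frame(
    genome_cov = gcov, ontarget_cov = ontarget, bp_spanning = bp,
    fusion_spanning = fusion_spanning,
    fold_ontarget = fold_enrichment(ontarget, gcov),
    fold_bp = fold_enrichment(bp, gcov),
    fold_fusion = fold_enrichment(fusion_spanning, gcov),
    directionality = read_directionality(segments, chrom, cut_pos,
                                         expected_direction))
}
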