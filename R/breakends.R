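#' Breakend pairs from the split alignments of one read
#'
#' Walks the read's aligned segments in read-coordinate order and emits
#' one breakend pair per adjacent segment pair. The retained side at each
#' junction end follows the genome-orientation rule: a segment aligned
#' '+' that ends at genomic `g` contributes `(chrom, g, L)` (its
#' genomic-left flank is retained in the derivative); a '+' segment
#' starting at genomic `g` contributes `(chrom, g, R)`; minus-strand
#' segments mirror (a '-' segment before the junction ends at its genomic
#' start, contributing side R; after the junction, side L).
#'
#' Ends are stored in canonical order (by chromosome, then position, then
#' side) so that reciprocal duplicates from reads traversing the junction
#' in either direction unify.
#'
#' @param segments data.frame of segments of a single read (as from
#'   [read_alignments()])
#' @return data.frame of breakend pairs: `read_id`, `chrom1`, `pos1`,
#'   `side1`, `chrom2`, `pos2`, `side2`, `mapq` (min of the two segments)
#' @export
breakends_from_read <- function(segments) {
  empty <- data.frame(read_id = character(), chrom1 = character(),
                      pos1 = integer(), side1 = character(),
                      chrom2 = character(), pos2 = integer(),
                      side2 = character(), mapq = integer(),
                      stringsAsFactors = FALSE)
  n <- nrow(segments)
  if (n < 2) return(empty)
  if (length(unique(segments$read_id)) != 1)
    stop("breakends_from_read expects segments of a single read")
  segments <- segments[order(segments$read_start), , drop = FALSE]
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- segments[i, ]
    b <- segments[i + 1L, ]
    # end contributed by the segment upstream of the junction in read order
    if (a$strand == "+") e1 <- list(a$chrom, a$ref_end, "L")
    else e1 <- list(a$chrom, a$ref_start, "R")
    # end contributed by the segment downstream of the junction
    if (b$strand == "+") e2 <- list(b$chrom, b$ref_start, "R")
    else e2 <- list(b$chrom, b$ref_end, "L")
    if (e1[[1]] > e2[[1]] ||
        (e1[[1]] == e2[[1]] &&
         (e1[[2]] > e2[[2]] || (e1[[2]] == e2[[2]] && e1[[3]] > e2[[3]])))) {
      tmp <- e1; e1 <- e2; e2 <- tmp
    }
    out[[i]] <- data.frame(
      read_id = a$read_id, chrom1 = e1[[1]], pos1 = as.integer(e1[[2]]),
      side1 = e1[[3]], chrom2 = e2[[1]], pos2 = as.integer(e2[[2]]),
      side2 = e2[[3]], mapq = min(a$mapq, b$mapq),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Extract breakend pairs from all reads of an alignment set
#'
#' @param segments data.frame from [read_alignments()] (any number of
#'   reads)
#' @return data.frame of breakend pairs, see [breakends_from_read()]
#' @export
extract_breakends <- function(segments) {
  parts <- lapply(split(segments, segments$read_id), breakends_from_read)
  res <- do.call(rbind, parts)
  if (is.null(res)) res <- breakends_from_read(segments[0, , drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Cluster breakend pairs into structural-variant calls
#'
#' Single-linkage clustering: two pairs merge iff their retained sides
#' match at both ends and both end positions are within
#' `cluster_distance`. Call positions are per-end medians of member
#' positions; support is the number of distinct read IDs (a read
#' supporting the same junction multiple times counts once); calls with
#' fewer than `min_support` distinct reads are removed. Pairs whose
#' minimum segment MAPQ is below `min_mapq` are excluded before
#' clustering. Per-end confidence-interval widths (max minus min member
#' position) above `ci_flag` raise `wide_ci` as a flag, not a filter.
#' Insertions are never emitted.
#'
#' @param pairs data.frame from [extract_breakends()]
#' @param cluster_distance maximum per-end distance for merging (bases)
#' @param min_support minimum distinct supporting reads; 1 is allowed for
#'   targeted re-queries of low-coverage loci
#' @param min_mapq minimum mapping quality of both segments of a pair
#' @param ci_flag per-end confidence-interval width above which the call
#'   is flagged
#' @return data.frame of class `sv_calls`: `id`, `chrom1`, `pos1`,
#'   `side1`, `chrom2`, `pos2`, `side2`, `svtype` (DEL/DUP/INV/BND),
#'   `support`, `ci1`, `ci2`, `wide_ci`, plus list-column
#'   `support_reads`
#' @export
cluster_breakends <- function(pairs, cluster_distance = 100,
                              min_support = 2, min_mapq = 12,
                              ci_flag = 300) {
  if (cluster_distance < 0) stop("cluster_distance must be >= 0")
  empty <- data.frame(id = character(), chrom1 = character(),
                      pos1 = integer(), side1 = character(),
                      chrom2 = character(), pos2 = integer(),
                      side2 = character(), svtype = character(),
                      support = integer(), ci1 = integer(),
                      ci2 = integer(), wide_ci = logical(),
                      stringsAsFactors = FALSE)
  empty$support_reads <- list()
  class(empty) <- c("sv_calls", "data.frame")
  if (nrow(pairs) == 0) return(empty)
  pairs <- pairs[pairs$mapq >= min_mapq, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  key <- paste(pairs$chrom1, pairs$side1, pairs$chrom2, pairs$side2,
               sep = "\r")
  calls <- list()
  for (k in unique(key)) {
    grp <- pairs[key == k, , drop = FALSE]
    comp <- linkage_components(grp$pos1, grp$pos2, cluster_distance)
    for (cl in unique(comp)) {
      m <- grp[comp == cl, , drop = FALSE]
      reads <- unique(m$read_id)
      if (length(reads) < min_support) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom1 = m$chrom1[1],
        pos1 = as.integer(floor(median(m$pos1))), side1 = m$side1[1],
        chrom2 = m$chrom2[1],
        pos2 = as.integer(floor(median(m$pos2))), side2 = m$side2[1],
        svtype = NA_character_, support = length(reads),
        ci1 = as.integer(max(m$pos1) - min(m$pos1)),
        ci2 = as.integer(max(m$pos2) - min(m$pos2)),
        wide_ci = NA, stringsAsFactors = FALSE)
      calls[[length(calls)]]$support_reads <- list(sort(reads))
    }
  }
  if (length(calls) == 0) return(empty)
  res <- do.call(rbind, calls)
  res$svtype <- classify_svtype(res)
  res$wide_ci <- pmax(res$ci1, res$ci2) > ci_flag
  res <- res[order(res$chrom1, res$pos1, res$chrom2, res$pos2), ,
             drop = FALSE]
  res <- cbind(id = sprintf("SV%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("sv_calls", "data.frame")
  res
}

# union-find single linkage on the merge predicate
# |dp1| <= d & |dp2| <= d (sides/chroms already grouped)
linkage_components <- function(pos1, pos2, d) {
  n <- length(pos1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    if (i == n) break
    for (j in (i + 1L):n) {
      if (abs(pos1[i] - pos1[j]) <= d && abs(pos2[i] - pos2[j]) <= d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

classify_svtype <- function(calls) {
  ifelse(calls$chrom1 != calls$chrom2, "BND",
    ifelse(calls$side1 == calls$side2, "INV",
      ifelse(calls$side1 == "L", "DEL", "DUP")))
}

#' Second-pass breakpoint refinement hook
#'
#' The reference pipeline re-maps fusion-supporting reads with a local
#' aligner and re-calls breakpoints on the remapped subset. Here
#' breakends are extracted from the already-split alignments in a single
#' pass, so this hook returns its input unchanged; it exists so a
#' re-mapping engine can be slotted in without touching callers.
#'
#' @param calls an `sv_calls` data.frame
#' @param segments the segments the calls were derived from
#' @return `calls`, unchanged
#' @export
refine_breakpoints <- function(calls, segments) {
  calls
}
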