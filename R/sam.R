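#' Read aligned segments from a SAM/BAM file
#'
#' Loads every primary and supplementary alignment record as one aligned
#' segment of its read; secondary alignments (flag 0x100) and unmapped
#' records are dropped. The read-coordinate interval of each segment is
#' reconstructed from CIGAR clips and, for minus-strand records, flipped
#' back to the original read orientation.
#'
#' Optional per-read sequencing start times (hours since run start) are
#' picked up from an `st` tag when present, as written by
#' [write_truth_sam()].
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @return data.frame with one row per segment: `read_id`, `chrom`,
#'   `ref_start`, `ref_end` (0-based half-open), `strand`, `read_start`,
#'   `read_end` (half-open on the original read), `read_len`, `mapq`,
#'   `is_supplementary`, `start_time` (NA when absent)
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    tag = "st",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0) {
    return(data.frame(read_id = character(), chrom = character(),
                      ref_start = integer(), ref_end = integer(),
                      strand = character(), read_start = integer(),
                      read_end = integer(), read_len = integer(),
                      mapq = integer(), is_supplementary = logical(),
                      start_time = numeric(), stringsAsFactors = FALSE))
  }
  if (any(is.na(rec$cigar) | rec$cigar == "*"))
    stop("mapped record without CIGAR (record ",
         which(is.na(rec$cigar) | rec$cigar == "*")[1], ")")
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  geom <- mapply(function(op, ln) {
    read_len <- sum(ln[op %in% c("M", "I", "S", "H", "=", "X")])
    k <- length(op)
    clip_left <- 0L
    i <- 1L
    while (i <= k && op[i] %in% c("S", "H")) { clip_left <- clip_left + ln[i]; i <- i + 1L }
    clip_right <- 0L
    i <- k
    while (i >= 1L && op[i] %in% c("S", "H")) { clip_right <- clip_right + ln[i]; i <- i - 1L }
    c(read_len, clip_left, clip_right)
  }, ops, lens)
  read_len <- geom[1, ]
  clip_left <- geom[2, ]
  clip_right <- geom[3, ]
  minus <- as.character(rec$strand) == "-"
  read_start <- ifelse(minus, clip_right, clip_left)
  read_end <- read_len - ifelse(minus, clip_left, clip_right)
  st <- rec$tag$st
  if (is.null(st)) st <- rep(NA_real_, n)
  data.frame(
    read_id = rec$qname,
    chrom = as.character(rec$rname),
    ref_start = rec$pos - 1L,
    ref_end = rec$pos - 1L + ref_width,
    strand = as.character(rec$strand),
    read_start = as.integer(read_start),
    read_end = as.integer(read_end),
    read_len = as.integer(read_len),
    mapq = as.integer(rec$mapq),
    is_supplementary = bitwAnd(rec$flag, 2048L) > 0L,
    start_time = as.numeric(st),
    stringsAsFactors = FALSE)
}
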