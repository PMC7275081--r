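#' Write SV calls as VCF 4.2 breakend records
#'
#' Each call is emitted as a mate pair of BND records. Internal breakend
#' coordinates are junction points in 0-based half-open space; the VCF
#' POS anchors on the retained base: side L emits POS = pos (the 1-based
#' last retained base left of the junction) and side R emits POS =
#' pos + 1 (the first retained base right of it).
#'
#' The ALT bracket encoding is fixed by the retained sides of the record
#' end (s) and its mate (t):
#' \describe{
#'   \item{s=L, t=R}{`N[mate[`}
#'   \item{s=L, t=L}{`N]mate]`}
#'   \item{s=R, t=L}{`]mate]N`}
#'   \item{s=R, t=R}{`[mate[N`}
#' }
#'
#' INFO carries `SVTYPE=BND`, `MATEID`, `SUPPORT` (distinct reads),
#' `SIMPLE_TYPE` (DEL/DUP/INV/BND), `CIPOS`/`CIEND` (0,width) and a
#' `WIDE_CI` flag; `RNAMES` lists the supporting read IDs so a parsed
#' file reconstructs the call set exactly.
#'
#' @param calls `sv_calls` data.frame from [cluster_breakends()]
#' @param path output path
#' @param contigs optional named integer vector of contig lengths for the
#'   header; contig names referenced by calls must be present when given
#' @param date logical; emit a fileDate header line (suppress for
#'   byte-identical replays)
#' @return `path`, invisibly
#' @export
write_sv_vcf <- function(calls, path, contigs = NULL, date = FALSE) {
  used <- unique(c(calls$chrom1, calls$chrom2))
  if (!is.null(contigs)) {
    unknown <- setdiff(used, names(contigs))
    if (length(unknown) > 0)
      stop("calls reference unknown contig(s): ",
           paste(unknown, collapse = ", "))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (date) paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    "##source=longfuse",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
    "##ALT=<ID=BND,Description=\"Breakend\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Distinct supporting reads\">",
    "##INFO=<ID=SIMPLE_TYPE,Number=1,Type=String,Description=\"Simple SV class (DEL/DUP/INV/BND)\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around mate POS\">",
    "##INFO=<ID=WIDE_CI,Number=0,Type=Flag,Description=\"Confidence interval wider than the ci_flag threshold\">",
    "##INFO=<ID=RNAMES,Number=.,Type=String,Description=\"Supporting read IDs\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    reads <- paste(cl$support_reads[[1]], collapse = ",")
    for (endi in 1:2) {
      if (endi == 1) {
        chrom <- cl$chrom1; pos <- cl$pos1; side <- cl$side1
        mchrom <- cl$chrom2; mpos <- cl$pos2; mside <- cl$side2
        ci_here <- cl$ci1; ci_mate <- cl$ci2
      } else {
        chrom <- cl$chrom2; pos <- cl$pos2; side <- cl$side2
        mchrom <- cl$chrom1; mpos <- cl$pos1; mside <- cl$side1
        ci_here <- cl$ci2; ci_mate <- cl$ci1
      }
      vpos <- vcf_pos(pos, side)
      mvpos <- vcf_pos(mpos, mside)
      mate_loc <- paste0(mchrom, ":", mvpos)
      alt <- switch(paste0(side, mside),
        LR = paste0("N[", mate_loc, "["),
        LL = paste0("N]", mate_loc, "]"),
        RL = paste0("]", mate_loc, "]N"),
        RR = paste0("[", mate_loc, "[N"))
      id <- paste0(cl$id, "_", endi)
      mate_id <- paste0(cl$id, "_", 3 - endi)
      info <- paste0(
        "SVTYPE=BND;MATEID=", mate_id,
        ";SUPPORT=", cl$support,
        ";SIMPLE_TYPE=", cl$svtype,
        ";CIPOS=0,", ci_here, ";CIEND=0,", ci_mate,
        if (isTRUE(cl$wide_ci)) ";WIDE_CI",
        ";RNAMES=", reads)
      rows <- c(rows, paste(chrom, vpos, id, "N", alt, ".", "PASS", info,
                            sep = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# VCF anchors on the retained base adjacent to the junction
vcf_pos <- function(pos, side) {
  if (side == "L") as.integer(pos) else as.integer(pos) + 1L
}

internal_pos <- function(vpos, side) {
  if (side == "L") as.integer(vpos) else as.integer(vpos) - 1L
}

#' Parse a breakend VCF written by [write_sv_vcf()]
#'
#' Reconstructs the `sv_calls` data.frame from the mate-pair records,
#' inverting the bracket encoding and the 1-based anchoring.
#'
#' @param path VCF file
#' @return an `sv_calls` data.frame (see [cluster_breakends()])
#' @export
read_sv_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- cluster_breakends(
    data.frame(read_id = character(), chrom1 = character(),
               pos1 = integer(), side1 = character(),
               chrom2 = character(), pos2 = integer(),
               side2 = character(), mapq = integer()))
  if (length(body) == 0) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  recs <- lapply(f, function(x) {
    info <- x[8]
    alt <- x[5]
    m <- regmatches(alt, regexec("([][])([^][]+)([][])", alt))[[1]]
    bracket <- m[2]
    loc <- m[3]
    side <- if (startsWith(alt, "N")) "L" else "R"
    mside <- if (bracket == "[") "R" else "L"
    get <- function(keypat) {
      hit <- regmatches(info, regexec(paste0("(?:^|;)", keypat, "=([^;]*)"),
                                      info))[[1]]
      if (length(hit) < 2) NA_character_ else hit[2]
    }
    list(chrom = x[1], vpos = as.integer(x[2]), id = x[3], side = side,
         mchrom = sub(":[0-9]+$", "", loc),
         mvpos = as.integer(sub("^.*:", "", loc)), mside = mside,
         mateid = get("MATEID"), support = as.integer(get("SUPPORT")),
         svtype = get("SIMPLE_TYPE"),
         ci = as.integer(strsplit(get("CIPOS"), ",")[[1]][2]),
         wide_ci = grepl("(^|;)WIDE_CI(;|$)", info),
         reads = strsplit(get("RNAMES"), ",")[[1]])
  })
  ids <- vapply(recs, `[[`, character(1), "id")
  base <- sub("_[12]$", "", ids)
  calls <- list()
  for (b in unique(base)) {
    pair <- recs[base == b]
    r1 <- pair[[which(endsWith(ids[base == b], "_1"))]]
    e1 <- list(chrom = r1$chrom, pos = internal_pos(r1$vpos, r1$side),
               side = r1$side, ci = r1$ci)
    e2 <- list(chrom = r1$mchrom, pos = internal_pos(r1$mvpos, r1$mside),
               side = r1$mside,
               ci = if (length(pair) == 2)
                 pair[[which(endsWith(ids[base == b], "_2"))]]$ci
               else NA_integer_)
    calls[[length(calls) + 1L]] <- local({
      df <- data.frame(id = b, chrom1 = e1$chrom, pos1 = e1$pos,
                       side1 = e1$side, chrom2 = e2$chrom, pos2 = e2$pos,
                       side2 = e2$side, svtype = r1$svtype,
                       support = r1$support, ci1 = e1$ci, ci2 = e2$ci,
                       wide_ci = r1$wide_ci, stringsAsFactors = FALSE)
      df$support_reads <- list(r1$reads)
      df
    })
  }
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  class(res) <- c("sv_calls", "data.frame")
  res
}
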