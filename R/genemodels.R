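#' Parse gene annotation from a GTF file
#'
#' Reads gene/transcript/exon/CDS features into an interval-indexed
#' `GeneModelSet`. GTF 1-based inclusive coordinates are converted to the
#' package-internal 0-based half-open convention. Chromosome names are
#' taken verbatim (no "chr" normalisation).
#'
#' The canonical transcript of a gene is the one with the longest total
#' CDS; ties are broken by lexicographically smallest transcript ID. Genes
#' with no coding transcript are retained (they are valid fusion partners;
#' CDS lengths report 0 downstream).
#'
#' @param path path to a GTF file with `gene_id` and `transcript_id`
#'   attributes. `gene` feature rows are optional: gene spans are inferred
#'   from their transcripts when absent.
#' @return an object of class `GeneModelSet`: a list with elements
#'   `genes` (named list of `Gene` objects) and `index` (a
#'   [GenomicRanges::GRanges] used for point queries).
#' @seealso [genes_at()], [locate()]
#' @export
read_gene_models <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "': ", conditionMessage(e))
  )
  df <- as.data.frame(gr)
  needed <- c("type", "gene_id")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("GTF '", path, "' lacks required attributes: ",
         paste(missing, collapse = ", "))
  if (!"transcript_id" %in% names(df)) df$transcript_id <- NA_character_
  if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
  # internal 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end

  feat <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (any(is.na(feat$transcript_id)))
    stop("GTF '", path, "': exon/CDS row without transcript_id")

  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    gfeat <- gdf[gdf$type %in% c("exon", "CDS"), , drop = FALSE]
    if (nrow(gfeat) == 0) next
    chrom <- as.character(gdf$seqnames[1])
    strand <- as.character(gdf$strand[1])
    if (!strand %in% c("+", "-"))
      stop("gene ", gid, ": strand must be '+' or '-'")
    transcripts <- list()
    for (tid in sort(unique(gfeat$transcript_id))) {
      tdf <- gfeat[gfeat$transcript_id == tid, , drop = FALSE]
      exons <- tdf[tdf$type == "exon", c("start0", "end0")]
      cds <- tdf[tdf$type == "CDS", c("start0", "end0")]
      exons <- exons[order(exons$start0), , drop = FALSE]
      cds <- cds[order(cds$start0), , drop = FALSE]
      rownames(exons) <- rownames(cds) <- NULL
      if (nrow(exons) == 0)
        stop("transcript ", tid, " of gene ", gid, " has no exons")
      if (nrow(exons) > 1 &&
          any(exons$start0[-1] < exons$end0[-nrow(exons)]))
        stop("transcript ", tid, ": overlapping exons")
      # every CDS block must be nested in an exon
      for (i in seq_len(nrow(cds))) {
        ok <- any(cds$start0[i] >= exons$start0 & cds$end0[i] <= exons$end0)
        if (!ok)
          stop("transcript ", tid, " of gene ", gid,
               ": CDS block [", cds$start0[i], ",", cds$end0[i],
               ") outside exons")
      }
      transcripts[[tid]] <- structure(
        list(id = tid, exons = exons, cds = cds),
        class = "Transcript")
    }
    cds_totals <- vapply(transcripts, function(tx)
      sum(tx$cds$end0 - tx$cds$start0), numeric(1))
    # longest total CDS wins; transcripts are already in lexicographic
    # order so which.max resolves ties toward the smaller ID
    canonical <- names(transcripts)[which.max(cds_totals)]
    grow <- gdf[gdf$type == "gene", , drop = FALSE]
    span_start <- if (nrow(grow) > 0) grow$start0[1] else min(gfeat$start0)
    span_end <- if (nrow(grow) > 0) grow$end0[1] else max(gfeat$end0)
    genes[[gid]] <- structure(
      list(id = gid, name = as.character(gdf$gene_name[1]), chrom = chrom,
           strand = strand, start = span_start, end = span_end,
           transcripts = transcripts, canonical = canonical),
      class = "Gene")
  }
  if (anyDuplicated(names(genes)) > 0) stop("duplicate gene IDs in GTF")
  new_gene_model_set(genes)
}

new_gene_model_set <- function(genes) {
  if (length(genes) > 0) {
    index <- GenomicRanges::GRanges(
      seqnames = vapply(genes, `[[`, character(1), "chrom"),
      ranges = IRanges::IRanges(
        start = vapply(genes, `[[`, numeric(1), "start") + 1L,
        end = vapply(genes, `[[`, numeric(1), "end")),
      gene_id = names(genes))
  } else {
    index <- GenomicRanges::GRanges()
  }
  structure(list(genes = genes, index = index), class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet with", length(x$genes), "genes on",
      length(unique(vapply(x$genes, `[[`, character(1), "chrom"))),
      "chromosomes\n")
  invisible(x)
}

#' @export
print.Gene <- function(x, ...) {
  cat(sprintf("Gene %s (%s) %s:%d-%d [%s], %d transcript(s), canonical %s\n",
              x$id, x$name, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts), x$canonical))
  invisible(x)
}

#' Genes overlapping a genomic position
#'
#' Returns every gene whose span contains `pos` (0-based). Overlapping
#' genes are all reported; downstream fusion candidacy tries each.
#' Unknown chromosomes yield an empty list rather than an error.
#'
#' @param models a `GeneModelSet` from [read_gene_models()]
#' @param chrom chromosome name (verbatim)
#' @param pos 0-based genomic position
#' @return list of `Gene` objects (possibly empty)
#' @export
genes_at <- function(models, chrom, pos) {
  stopifnot(inherits(models, "GeneModelSet"))
  if (length(models$genes) == 0) return(list())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, models$index, ignore.strand = TRUE))
  ids <- models$index$gene_id[S4Vectors::subjectHits(hits)]
  unname(models$genes[ids])
}

#' Locate a position within a gene's transcript structure
#'
#' Reports the exon or intron containing `pos`, numbered in transcript
#' orientation starting at 1, and the number of CDS bases strictly 5' (in
#' transcript orientation) of `pos` on the chosen transcript.
#'
#' Positions are bases in 0-based coordinates; half-open exon intervals
#' make boundary assignment deterministic (the base at an exon start
#' belongs to the exon; the base at an exon end to the following intron).
#'
#' @param gene a `Gene`
#' @param pos 0-based position, must lie within the gene span
#' @param transcript transcript ID; default the gene's canonical transcript
#' @return list with `feature` ("exon" or "intron"), `index` (1-based in
#'   transcript orientation), `label` (e.g. "exon 2"), and `cds_offset`
#'   (CDS bases strictly transcript-5' of `pos`; 0 when `pos` precedes the
#'   CDS start)
#' @export
locate <- function(gene, pos, transcript = NULL) {
  stopifnot(inherits(gene, "Gene"))
  if (pos < gene$start || pos >= gene$end)
    stop("position ", pos, " outside span of gene ", gene$id)
  tid <- if (is.null(transcript)) gene$canonical else transcript
  tx <- gene$transcripts[[tid]]
  if (is.null(tx)) stop("unknown transcript ", tid, " for gene ", gene$id)
  ex <- tx$exons
  n <- nrow(ex)
  in_exon <- which(pos >= ex$start0 & pos < ex$end0)
  if (length(in_exon) == 1) {
    genomic_idx <- in_exon
    feature <- "exon"
  } else {
    # intron i (genomic) lies between exon i and i+1
    genomic_idx <- findInterval(pos, ex$end0)
    if (genomic_idx < 1 || genomic_idx >= n) {
      # pos inside gene span but outside the transcript's exon range:
      # clamp to terminal exon context
      feature <- "exon"
      genomic_idx <- if (pos < ex$start0[1]) 1L else n
    } else {
      feature <- "intron"
    }
  }
  index <- if (gene$strand == "+") genomic_idx else {
    if (feature == "exon") n - genomic_idx + 1L else (n - 1L) - genomic_idx + 1L
  }
  # CDS bases strictly transcript-5' of pos: coord < pos on '+',
  # coord > pos on '-'
  offset <- if (gene$strand == "+")
    cds_flank_length(gene, pos, "left", transcript = tid)
  else cds_flank_length(gene, pos + 1, "right", transcript = tid)
  list(feature = feature, index = as.integer(index),
       label = paste(feature, index), cds_offset = offset)
}

#' CDS bases on one genomic flank of a junction coordinate
#'
#' Counts canonical-transcript CDS bases strictly left (`coord < junction`)
#' or right (`coord >= junction`) of a 0-based junction coordinate. Used
#' both for `cds_offset` in [locate()] and for fused-CDS composition.
#'
#' @param gene a `Gene`
#' @param junction 0-based junction coordinate (between bases
#'   `junction - 1` and `junction`)
#' @param flank "left" or "right"
#' @param transcript transcript ID, default canonical
#' @return integer number of CDS bases on that flank
#' @export
cds_flank_length <- function(gene, junction, flank = c("left", "right"),
                             transcript = NULL) {
  flank <- match.arg(flank)
  tid <- if (is.null(transcript)) gene$canonical else transcript
  cds <- gene$transcripts[[tid]]$cds
  if (is.null(cds) || nrow(cds) == 0) return(0L)
  if (flank == "left") {
    as.integer(sum(pmax(0, pmin(cds$end0, junction) - cds$start0)))
  } else {
    as.integer(sum(pmax(0, cds$end0 - pmax(cds$start0, junction))))
  }
}

#' Total CDS length of a gene's canonical transcript
#' @param gene a `Gene`
#' @param transcript transcript ID, default canonical
#' @return integer CDS length in bases (0 for non-coding genes)
#' @export
gene_cds_length <- function(gene, transcript = NULL) {
  tid <- if (is.null(transcript)) gene$canonical else transcript
  cds <- gene$transcripts[[tid]]$cds
  if (is.null(cds) || nrow(cds) == 0) return(0L)
  as.integer(sum(cds$end0 - cds$start0))
}
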