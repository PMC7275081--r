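# fixtures are built in code; nothing is read from disk except what the
# helpers themselves write to tempfiles

gtf_line <- function(chrom, type, start0, end0, strand, gene, tx = NULL) {
  attrs <- paste0("gene_id \"", gene, "\"; ",
                  if (!is.null(tx)) paste0("transcript_id \"", tx, "\"; "),
                  "gene_name \"", gene, "\";")
  paste(chrom, "test", type, start0 + 1L, end0, ".", strand, ".", attrs,
        sep = "\t")
}

write_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

# two-exon '+' gene with CDS equal to its exons:
# exons [1000,1200), [2000,2400) on chr1
plus_gene_gtf <- function(gene = "geneA", chrom = "chr1") {
  c(gtf_line(chrom, "gene", 1000, 2400, "+", gene),
    gtf_line(chrom, "transcript", 1000, 2400, "+", gene, "tA"),
    gtf_line(chrom, "exon", 1000, 1200, "+", gene, "tA"),
    gtf_line(chrom, "exon", 2000, 2400, "+", gene, "tA"),
    gtf_line(chrom, "CDS", 1000, 1200, "+", gene, "tA"),
    gtf_line(chrom, "CDS", 2000, 2400, "+", gene, "tA"))
}

# construct a Gene object directly (for orientation/CDS truth tables)
make_gene <- function(id, chrom, strand, exons, cds = exons) {
  ex <- data.frame(start0 = vapply(exons, `[[`, numeric(1), 1),
                   end0 = vapply(exons, `[[`, numeric(1), 2))
  cd <- if (length(cds) == 0)
    data.frame(start0 = numeric(0), end0 = numeric(0))
  else data.frame(start0 = vapply(cds, `[[`, numeric(1), 1),
                  end0 = vapply(cds, `[[`, numeric(1), 2))
  tx <- structure(list(id = paste0(id, ".t"), exons = ex, cds = cd),
                  class = "Transcript")
  structure(list(id = id, name = id, chrom = chrom, strand = strand,
                 start = min(ex$start0), end = max(ex$end0),
                 transcripts = setNames(list(tx), tx$id),
                 canonical = tx$id),
            class = "Gene")
}

# one-row sv_calls data.frame
make_call <- function(chrom1, pos1, side1, chrom2, pos2, side2,
                      reads = c("r1", "r2"), id = "SV001",
                      wide_ci = FALSE) {
  df <- data.frame(id = id, chrom1 = chrom1, pos1 = as.integer(pos1),
                   side1 = side1, chrom2 = chrom2,
                   pos2 = as.integer(pos2), side2 = side2,
                   svtype = NA_character_, support = length(reads),
                   ci1 = 0L, ci2 = 0L, wide_ci = wide_ci,
                   stringsAsFactors = FALSE)
  df$svtype <- longfuse:::classify_svtype(df)
  df$support_reads <- list(sort(reads))
  class(df) <- c("sv_calls", "data.frame")
  df
}

# breakend pair rows for cluster_breakends
make_pairs <- function(pos1, pos2, side1 = "L", side2 = "R",
                       chrom1 = "chr1", chrom2 = "chr2",
                       reads = paste0("r", seq_along(pos1)), mapq = 60) {
  n <- length(pos1)
  data.frame(read_id = rep(reads, length.out = n),
             chrom1 = rep(chrom1, length.out = n),
             pos1 = as.integer(pos1),
             side1 = rep(side1, length.out = n),
             chrom2 = rep(chrom2, length.out = n),
             pos2 = as.integer(pos2),
             side2 = rep(side2, length.out = n),
             mapq = rep(mapq, length.out = n), stringsAsFactors = FALSE)
}

# minimal SAM text file with given records
write_sam <- function(records, contigs = c(chr1 = 100000L, chr2 = 100000L)) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                   as.integer(contigs)))
  writeLines(c(hdr, records), path)
  path
}

sam_rec <- function(qname, flag, rname, pos1, cigar, mapq = 60,
                    seq = "*", tags = character(0)) {
  paste(c(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, seq, "*",
          tags), collapse = "\t")
}

# a simulated fusion scenario shared by several tests: GENEA (chrA '+')
# fused to GENEC (chrB '+') with the junction in intron 2 of both
simple_fusion_scenario <- function(seed = 11, reads_per_cut = 15,
                                   background = 0) {
  gb <- build_genome(seed = seed)
  rr <- apply_rearrangement(gb$genome, list(
    list(op = "JOIN", chrom1 = "chrA", pos1 = 12800L, side1 = "L",
         chrom2 = "chrB", pos2 = 12000L, side2 = "R", name = "der1")))
  cuts <- data.frame(haplotype = "der1", pos = 9000L,
                     direction = "right", stringsAsFactors = FALSE)
  sim <- simulate_reads(gb$genome, rr, cuts,
                        sim_config(capture_reads_per_cut = reads_per_cut,
                                   background_cov = background),
                        seed = seed)
  sam <- tempfile(fileext = ".sam")
  write_truth_sam(sim, gb$genome, sam)
  list(gb = gb, rr = rr, sim = sim, sam = sam)
}
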