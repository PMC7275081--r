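models_two_genes <- function() {
  lines <- c(plus_gene_gtf("geneA", "chr1"), plus_gene_gtf("geneB", "chr2"))
  read_gene_models(write_gtf(lines))
}

test_that("candidate selection requires two distinct genic ends", {
  models <- models_two_genes()
  # ends in geneA and geneB
  c1 <- make_call("chr1", 1500, "L", "chr2", 1500, "R")
  expect_equal(nrow(candidate_fusions(c1, models)), 1)
  # both ends in the same gene (intragenic inversion)
  c2 <- make_call("chr1", 1100, "L", "chr1", 2200, "L")
  expect_equal(nrow(candidate_fusions(c2, models)), 0)
  # intergenic end stays out of candidacy
  c3 <- make_call("chr1", 50000, "L", "chr2", 1500, "R")
  expect_equal(nrow(candidate_fusions(c3, models)), 0)
})

test_that("overlapping genes at one end yield one candidate per pair", {
  lines <- c(plus_gene_gtf("geneA", "chr1"), plus_gene_gtf("geneC", "chr1"),
             plus_gene_gtf("geneB", "chr2"))
  models <- read_gene_models(write_gtf(lines))
  cl <- make_call("chr1", 1500, "L", "chr2", 1500, "R")
  cands <- candidate_fusions(cl, models)
  expect_equal(nrow(cands), 2)
  expect_setequal(cands$gene1, c("geneA", "geneC"))
})

test_that("orientation examples follow the continuity truth table", {
  gA <- make_gene("A", "chr1", "+", list(c(1000, 2000)))
  gBp <- make_gene("B", "chr2", "+", list(c(1000, 2000)))
  gBm <- make_gene("B", "chr2", "-", list(c(1000, 2000)))
  # A '+' side L with B '+' side R: A is 5', B is 3'
  f <- orient_fusion(make_call("chr1", 1500, "L", "chr2", 1500, "R"),
                     gA, gBp)
  expect_length(f, 1)
  expect_equal(f[[1]]$gene5$id, "A")
  expect_equal(f[[1]]$gene3$id, "B")
  # A '+' side L with B '-' side L: B retains its transcript-downstream,
  # genomic-left part, so A is still 5'
  f <- orient_fusion(make_call("chr1", 1500, "L", "chr2", 1500, "L"),
                     gA, gBm)
  expect_length(f, 1)
  expect_equal(f[[1]]$gene5$id, "A")
  # both '+' both side L: head-to-head, rejected
  f <- orient_fusion(make_call("chr1", 1500, "L", "chr2", 1500, "L"),
                     gA, gBp)
  expect_length(f, 0)
})

test_that("CDS composition sums flank lengths and sets frame flags", {
  # geneA '+': CDS [1000,1200)+[2000,2400); break in intron keeps 200
  # geneB '+': same structure; break at 2200 keeps 200 of exon 2 -> 400
  models <- models_two_genes()
  cl <- make_call("chr1", 1500, "L", "chr2", 2000, "R")
  fus <- orient_fusion(cl, models$genes$geneA, models$genes$geneB)
  fu <- compose_cds(fus[[1]])
  expect_equal(fu$cds5_len, 200)
  expect_equal(fu$cds3_len, 400)
  expect_equal(fu$fused_cds_len, 600)
  expect_false("OUT_OF_FRAME" %in% fu$flags)
  # shift the 3' breakpoint by one base: 599 total, out of frame
  cl2 <- make_call("chr1", 1500, "L", "chr2", 2001, "R")
  fu2 <- compose_cds(orient_fusion(cl2, models$genes$geneA,
                                   models$genes$geneB)[[1]])
  expect_equal(fu2$fused_cds_len, 599)
  expect_true("OUT_OF_FRAME" %in% fu2$flags)
})

test_that("non-coding partners raise NO_CDS, upstream breaks PROMOTER_5", {
  gA <- make_gene("A", "chr1", "+", list(c(1000, 2000)),
                  cds = list(c(1300, 1600)))
  gNC <- make_gene("N", "chr2", "+", list(c(1000, 2000)), cds = list())
  # breakpoint upstream of the CDS start of a coding 5' gene
  fu <- compose_cds(orient_fusion(make_call("chr1", 1100, "L",
                                            "chr2", 1500, "R"),
                                  gA, gNC)[[1]])
  expect_equal(fu$cds5_len, 0)
  expect_true("PROMOTER_5" %in% fu$flags)
  expect_true("NO_CDS" %in% fu$flags)     # 3' partner is non-coding
  expect_false("OUT_OF_FRAME" %in% fu$flags)
})

test_that("reciprocal fusions are mutually linked, others are not", {
  gA <- make_gene("A", "chr1", "+", list(c(1000, 2000)))
  gB <- make_gene("B", "chr2", "+", list(c(1000, 2000)))
  gC <- make_gene("C", "chr3", "+", list(c(1000, 2000)))
  mk <- function(g5, g3, id) {
    fu <- orient_fusion(make_call(g5$chrom, 1500, "L", g3$chrom, 1500, "R"),
                        g5, g3)[[1]]
    fu <- compose_cds(fu)
    fu$id <- id
    fu
  }
  ab <- mk(gA, gB, "FG1"); ba <- mk(gB, gA, "FG2"); ac <- mk(gA, gC, "FG3")
  linked <- link_reciprocals(list(ab, ba, ac))
  expect_true("RECIPROCAL_OF:FG2" %in% linked[[1]]$flags)
  expect_true("RECIPROCAL_OF:FG1" %in% linked[[2]]$flags)
  expect_false(any(grepl("RECIPROCAL", linked[[3]]$flags)))
  # a lone fusion gains no flag
  expect_false(any(grepl("RECIPROCAL", link_reciprocals(list(ab))[[1]]$flags)))
})

test_that("calls sharing reads within 1 kb are chain-annotated", {
  c1 <- make_call("chr1", 1000, "L", "chr1", 1030, "R",
                  reads = c("r1", "r2"))
  c2 <- make_call("chr1", 1230, "L", "chr2", 5000, "R",
                  reads = c("r1", "r2"), id = "SV002")
  c3 <- make_call("chr3", 9000, "L", "chr4", 9000, "R",
                  reads = c("r9", "r8"), id = "SV003")
  calls <- rbind(c1, c2, c3)
  class(calls) <- c("sv_calls", "data.frame")
  ch <- annotate_chains(calls)
  expect_equal(ch, c("SV002", "SV001", NA))
})

test_that("overview has the fixed column set and round-trips", {
  models <- models_two_genes()
  cl <- make_call("chr1", 1500, "L", "chr2", 2000, "R",
                  reads = c("r1", "r2", "r3"))
  fus <- call_fusions(cl, models)
  path <- tempfile(fileext = ".tsv")
  ov <- fusion_overview(fus, path)
  expect_equal(names(ov),
               c("gene5", "gene3", "locus5", "locus3", "bp5", "bp3",
                 "support", "cds5_len", "cds3_len", "fused_cds_len",
                 "flags", "primer_fwd", "primer_rev"))
  back <- read_fusion_overview(path)
  expect_equal(back[names(back) != "primer_fwd" &
                      names(back) != "primer_rev"],
               ov[names(ov) != "primer_fwd" & names(ov) != "primer_rev"])
  expect_equal(back$support, 3)
  expect_equal(back$bp5, "chr1:1500")
  expect_equal(back$bp3, "chr2:2001")
  # empty input: header-only table
  empty <- cluster_breakends(make_pairs(integer(0), integer(0)))
  ov0 <- fusion_overview(call_fusions(empty, models))
  expect_equal(nrow(ov0), 0)
  expect_equal(names(ov0), names(ov))
})

test_that("overview support counts distinct reads from the SV layer", {
  models <- models_two_genes()
  # read r1 supports the junction twice; overview support must be 2
  p <- make_pairs(pos1 = c(1500, 1500, 1510), pos2 = c(2000, 2000, 2010),
                  reads = c("r1", "r1", "r2"))
  calls <- cluster_breakends(p)
  ov <- fusion_overview(call_fusions(calls, models))
  expect_equal(ov$support, 2)
})
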