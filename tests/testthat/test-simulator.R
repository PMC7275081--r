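test_that("genome building is deterministic and parser-valid", {
  d1 <- tempfile("g1"); d2 <- tempfile("g2")
  g1 <- build_genome(seed = 4, dir = d1)
  g2 <- build_genome(seed = 4, dir = d2)
  expect_identical(readLines(g1$fasta), readLines(g2$fasta))
  expect_identical(readLines(g1$gtf), readLines(g2$gtf))
  g3 <- build_genome(seed = 5, dir = tempfile())
  expect_false(identical(as.character(g1$genome[[1]]),
                         as.character(g3$genome[[1]])))
  # requested genes all appear as gene records
  gtf <- readLines(g1$gtf)
  expect_equal(sum(grepl("\tgene\t", gtf)),
               nrow(genome_config()$genes))
  # CDS nested in exons: the strict parser accepts the file
  models <- read_gene_models(g1$gtf)
  expect_length(models$genes, nrow(genome_config()$genes))
  expect_equal(gene_cds_length(models$genes$GENEN), 0)
})

test_that("overlapping gene placements are rejected", {
  cfg <- genome_config(genes = data.frame(
    name = c("G1", "G2"), chrom = "chrA", start = c(1000L, 1500L),
    strand = "+", n_exons = 2L, exon_len = 300L, intron_len = 500L,
    coding = TRUE, stringsAsFactors = FALSE))
  expect_error(build_genome(cfg, seed = 1), "overlapping")
})

test_that("rearrangement surgery matches hand-built toy sequences", {
  toy <- Biostrings::DNAStringSet(c(
    c1 = paste(rep(c("A", "C"), 100), collapse = ""),
    c2 = paste(rep(c("G", "T"), 100), collapse = "")))
  # reciprocal translocation at c1:120 / c2:80
  rr <- apply_rearrangement(toy, list(
    list(op = "JOIN", chrom1 = "c1", pos1 = 120L, side1 = "L",
         chrom2 = "c2", pos2 = 80L, side2 = "R", name = "derA"),
    list(op = "JOIN", chrom1 = "c1", pos1 = 120L, side1 = "R",
         chrom2 = "c2", pos2 = 80L, side2 = "L", name = "derB")))
  s1 <- as.character(toy[["c1"]]); s2 <- as.character(toy[["c2"]])
  expect_equal(as.character(rr$derivatives$derA$seq),
               paste0(substring(s1, 1, 120), substring(s2, 81, 200)))
  # derB retains the other two flanks (as one orientation of the
  # reciprocal product)
  rcc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(as.character(rr$derivatives$derB$seq),
               paste0(rcc(substring(s1, 121, 200)),
                      rcc(substring(s2, 1, 80))))
  # two truth junctions with mirrored retained sides
  expect_equal(nrow(rr$junctions), 2)
  expect_setequal(paste(rr$junctions$side1, rr$junctions$side2),
                  c("L R", "R L"))
  expect_error(apply_rearrangement(toy, list(
    list(op = "DEL", chrom = "c1", start = 150L, end = 900L))),
    "out of bounds")
})

test_that("empty rearrangement returns the reference unchanged", {
  toy <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTAC"))
  rr <- apply_rearrangement(toy)
  expect_equal(nrow(rr$junctions), 0)
  expect_equal(as.character(rr$derivatives$c1$seq), "ACGTACGTAC")
})

test_that("deletion+inversion+fusion produces the complex-event junctions", {
  gb <- build_genome(seed = 7)
  rr <- apply_rearrangement(gb$genome, list(
    list(op = "DEL", chrom = "chrA", start = 12000L, end = 12030L),
    list(op = "INV", chrom = "chrA", start = 12230L, end = 12415L),
    list(op = "JOIN", chrom1 = "chrA", pos1 = 12600L, side1 = "L",
         chrom2 = "chrB", pos2 = 12000L, side2 = "R", name = "der1")))
  j <- rr$junctions
  expect_equal(nrow(j), 4)
  expect_setequal(j$svtype, c("DEL", "INV", "BND"))
  del <- j[j$svtype == "DEL", ]
  expect_equal(del$pos2 - del$pos1, 30)
  inv <- j[j$svtype == "INV", ]
  expect_equal(unique(inv$pos2 - inv$pos1), 185)
  # when the deleted segment directly abuts the inverted one, the two
  # junctions merge into the single adjacency a read would observe
  rr2 <- apply_rearrangement(gb$genome, list(
    list(op = "DEL", chrom = "chrA", start = 12000L, end = 12030L),
    list(op = "INV", chrom = "chrA", start = 12030L, end = 12215L),
    list(op = "JOIN", chrom1 = "chrA", pos1 = 12600L, side1 = "L",
         chrom2 = "chrB", pos2 = 12000L, side2 = "R", name = "der1")))
  expect_equal(nrow(rr2$junctions), 3)
})

test_that("simulated reads honor cut sites, direction and length model", {
  gb <- build_genome(seed = 13)
  cuts <- data.frame(haplotype = "chrA", pos = 50000L,
                     direction = "right", stringsAsFactors = FALSE)
  cfg <- sim_config(capture_reads_per_cut = 1000, background_cov = 0,
                    read_len_sdlog = 0.3)
  sim <- simulate_reads(gb$genome, NULL, cuts, cfg, seed = 2)
  first <- sim$provenance[sim$provenance$read_start == 0, ]
  expect_true(all(abs(first$ref_start - 50000) <= 5))
  expect_true(all(first$strand == "+"))
  # law of large numbers: mean length within 10% of the configured mean
  expect_lt(abs(mean(nchar(sim$reads)) - 9900) / 9900, 0.1)
  # timestamps inside the run, front-loaded by the exponential model
  expect_true(all(sim$times >= 0 & sim$times <= 48))
  expect_gt(mean(sim$times <= 12), 0.6)
})

test_that("chimera-free simulations have no orphan junctions", {
  sc <- simple_fusion_scenario(seed = 17, reads_per_cut = 10,
                               background = 0.1)
  prov <- sc$sim$provenance
  expect_false(any(prov$is_chimera))
  # every multi-segment read maps the truth junction
  multi <- names(which(table(prov$read_id) > 1))
  for (id in multi) {
    p <- prov[prov$read_id == id, ]
    p <- p[order(p$read_start), ]
    expect_equal(p$ref_end[1], 12800)
    expect_equal(p$ref_start[2], 12000)
  }
})

test_that("chimeric reads add junctions absent from the truth set", {
  gb <- build_genome(seed = 19)
  cfg <- sim_config(capture_reads_per_cut = 0, background_cov = 0.3,
                    chimera_per_1000 = 300)
  sim <- simulate_reads(gb$genome, NULL, NULL, cfg, seed = 3)
  expect_gt(sum(sim$provenance$is_chimera), 0)
})

test_that("truth SAM round-trips through the alignment reader", {
  sc <- simple_fusion_scenario(seed = 23, reads_per_cut = 5)
  segs <- read_alignments(sc$sam)
  prov <- sc$sim$provenance
  expect_equal(nrow(segs), nrow(prov))
  key <- function(df) paste(df$read_id, df$chrom, df$ref_start,
                            df$ref_end, df$strand, df$read_start,
                            df$read_end)
  expect_setequal(key(segs), key(prov))
  expect_true(all(segs$mapq == 60))
  # start times survive the round trip
  t <- segs$start_time[match(names(sc$sim$times), segs$read_id)]
  expect_equal(t, unname(round(sc$sim$times, 4)), tolerance = 1e-3)
})

test_that("identical config and seed replay identical simulations", {
  s1 <- simple_fusion_scenario(seed = 29, reads_per_cut = 5)
  s2 <- simple_fusion_scenario(seed = 29, reads_per_cut = 5)
  expect_identical(s1$sim$reads, s2$sim$reads)
  expect_identical(s1$sim$provenance, s2$sim$provenance)
  expect_identical(readLines(s1$sam), readLines(s2$sam))
})

test_that("substitution errors perturb sequences but not provenance", {
  gb <- build_genome(seed = 13)
  cuts <- data.frame(haplotype = "chrA", pos = 50000L,
                     direction = "right", stringsAsFactors = FALSE)
  clean <- simulate_reads(gb$genome, NULL, cuts,
                          sim_config(capture_reads_per_cut = 5,
                                     background_cov = 0), seed = 6)
  noisy <- simulate_reads(gb$genome, NULL, cuts,
                          sim_config(capture_reads_per_cut = 5,
                                     background_cov = 0,
                                     error_rate = 0.05), seed = 6)
  expect_identical(clean$provenance, noisy$provenance)
  expect_identical(nchar(clean$reads), nchar(noisy$reads))
  mism <- mapply(function(a, b) {
    ab <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
    mean(ab != bb)
  }, clean$reads, noisy$reads)
  expect_gt(mean(mism), 0.03)
  expect_lt(mean(mism), 0.07)
})
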