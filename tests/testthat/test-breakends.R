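test_that("SAM reading keeps primary+supplementary, drops secondary", {
  seqA <- paste(rep("A", 12000), collapse = "")
  sam <- write_sam(c(
    sam_rec("r1", 0, "chr1", 10001, "8000M4000S", seq = seqA),
    sam_rec("r1", 2048, "chr2", 5001, "8000S4000M", seq = seqA),
    sam_rec("r2", 256, "chr1", 20001, "1000M", seq = "*")))
  segs <- read_alignments(sam)
  expect_equal(nrow(segs), 2)
  expect_equal(unique(segs$read_id), "r1")
  expect_equal(segs$ref_start, c(10000, 5000))
  expect_equal(segs$ref_end, c(18000, 9000))
  expect_equal(segs$read_start, c(0, 8000))
  expect_equal(segs$read_end, c(8000, 12000))
  expect_equal(segs$is_supplementary, c(FALSE, TRUE))
})

test_that("minus-strand read intervals flip to original-read orientation", {
  # SAM stores the reverse complement; CIGAR 2000S3000M1000S on '-'
  # covers SAM-read [2000,5000) of a 6000 nt read, i.e. original-read
  # [6000-5000, 6000-2000) = [1000,4000) by hand clip arithmetic
  sam <- write_sam(sam_rec("r1", 16, "chr1", 1001, "2000S3000M1000S",
                           seq = paste(rep("C", 6000), collapse = "")))
  segs <- read_alignments(sam)
  expect_equal(segs$strand, "-")
  expect_equal(segs$read_start, 1000)
  expect_equal(segs$read_end, 4000)
  expect_equal(segs$read_len, 6000)
  expect_equal(segs$ref_start, 1000)
  expect_equal(segs$ref_end, 4000)
})

test_that("breakends_from_read applies the retained-side rule", {
  segs <- data.frame(
    read_id = "r1", chrom = c("chr1", "chr2"),
    ref_start = c(10000L, 5000L), ref_end = c(18000L, 9000L),
    strand = "+", read_start = c(0L, 8000L), read_end = c(8000L, 12000L),
    read_len = 12000L, mapq = 60L, is_supplementary = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  pairs <- breakends_from_read(segs)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$chrom1, "chr1")
  expect_equal(pairs$pos1, 18000)
  expect_equal(pairs$side1, "L")
  expect_equal(pairs$chrom2, "chr2")
  expect_equal(pairs$pos2, 5000)
  expect_equal(pairs$side2, "R")
  # single segment: no junction
  expect_equal(nrow(breakends_from_read(segs[1, ])), 0)
  # three segments: exactly two pairs
  seg3 <- rbind(segs, within(segs[2, ], {
    chrom <- "chr1"; ref_start <- 30000L; ref_end <- 32000L
    read_start <- 12000L; read_end <- 14000L
  }))
  seg3$read_len <- 14000L
  expect_equal(nrow(breakends_from_read(seg3)), 2)
})

test_that("canonical end ordering makes pairs traversal-independent", {
  # the same junction read in the opposite direction: segments map '-'
  # and appear in swapped read order
  fwd <- data.frame(
    read_id = "f", chrom = c("chr1", "chr2"),
    ref_start = c(10000L, 5000L), ref_end = c(18000L, 9000L),
    strand = "+", read_start = c(0L, 8000L), read_end = c(8000L, 12000L),
    read_len = 12000L, mapq = 60L, is_supplementary = FALSE,
    stringsAsFactors = FALSE)
  rev <- data.frame(
    read_id = "r", chrom = c("chr2", "chr1"),
    ref_start = c(5000L, 10000L), ref_end = c(9000L, 18000L),
    strand = "-", read_start = c(0L, 4000L), read_end = c(4000L, 12000L),
    read_len = 12000L, mapq = 60L, is_supplementary = FALSE,
    stringsAsFactors = FALSE)
  pf <- breakends_from_read(fwd)
  pr <- breakends_from_read(rev)
  cols <- c("chrom1", "pos1", "side1", "chrom2", "pos2", "side2")
  expect_equal(pf[, cols], pr[, cols])
})

test_that("clustering merges within distance and counts distinct reads", {
  # offset 100 at both ends, same sides: one call of support 2
  p <- make_pairs(pos1 = c(18000, 18100), pos2 = c(5000, 5100))
  calls <- cluster_breakends(p)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$support, 2)
  expect_equal(calls$pos1, 18050)
  # offset 101: two singleton clusters, both below default min_support
  p2 <- make_pairs(pos1 = c(18000, 18101), pos2 = c(5000, 5101))
  expect_equal(nrow(cluster_breakends(p2)), 0)
  expect_equal(nrow(cluster_breakends(p2, min_support = 1)), 2)
  expect_error(cluster_breakends(p, cluster_distance = -1), "cluster_distance")
})

test_that("pairs below min_mapq are excluded before clustering", {
  p <- make_pairs(pos1 = c(18000, 18000), pos2 = c(5000, 5000),
                  mapq = c(11, 12))
  calls <- cluster_breakends(p, min_support = 1)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$support, 1)
  expect_equal(calls$support_reads[[1]], "r2")
})

test_that("a read supporting the same junction twice counts once", {
  p <- make_pairs(pos1 = c(18000, 18000, 18010), pos2 = c(5000, 5000, 5010),
                  reads = c("r1", "r1", "r2"))
  calls <- cluster_breakends(p)
  expect_equal(calls$support, 2)
})

test_that("sides must match for merging and svtype is classified", {
  p <- make_pairs(pos1 = c(1000, 1000), pos2 = c(5000, 5000),
                  side1 = c("L", "L"), side2 = c("R", "L"),
                  chrom1 = "chr1", chrom2 = "chr1")
  calls <- cluster_breakends(p, min_support = 1)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$svtype, c("DEL", "INV"))
  pd <- make_pairs(pos1 = 1000, pos2 = 5000, side1 = "R", side2 = "L",
                   chrom1 = "chr1", chrom2 = "chr1")
  expect_equal(cluster_breakends(pd, min_support = 1)$svtype, "DUP")
})

test_that("wide confidence intervals flag but do not filter", {
  pos1 <- c(18000, 18100, 18200, 18300, 18400)
  p <- make_pairs(pos1 = pos1, pos2 = rep(5000, 5))
  calls <- cluster_breakends(p)  # chain-merges via single linkage
  expect_equal(nrow(calls), 1)
  expect_equal(calls$ci1, 400)
  expect_true(calls$wide_ci)
  expect_equal(calls$support, 5)
})

test_that("clustering equals a graph connected-components oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(99, {
    for (rep in 1:5) {
      n <- sample(10:50, 1)
      p <- make_pairs(
        pos1 = sample.int(2000, n, replace = TRUE),
        pos2 = sample.int(2000, n, replace = TRUE),
        side1 = sample(c("L", "R"), n, replace = TRUE),
        side2 = "R", reads = paste0("r", seq_len(n)))
      d <- 100
      adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
        p$side1[i] == p$side1[j] &&
          abs(p$pos1[i] - p$pos1[j]) <= d &&
          abs(p$pos2[i] - p$pos2[j]) <= d))
      comp <- igraph::components(
        igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
      oracle_calls <- sum(table(comp$membership) >= 1)
      calls <- cluster_breakends(p, min_support = 1, min_mapq = 0)
      expect_equal(nrow(calls), oracle_calls)
      # per-cluster medians agree
      oracle_pos <- sort(vapply(seq_len(comp$no), function(k)
        floor(median(p$pos1[comp$membership == k])), numeric(1)))
      expect_equal(sort(calls$pos1), as.integer(oracle_pos))
    }
  })
})
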