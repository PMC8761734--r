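# Interval arithmetic, TSS distance convention and promoter annotation.

test_that("overlap length handles identity, adjacency and chromosome mismatch", {
  a <- intervals("chr1", 10, 20)
  expect_equal(overlap_bp(a, a), 11L)                      # inclusive length
  expect_equal(overlap_bp(a, intervals("chr1", 21, 30)), 0L)
  expect_equal(overlap_bp(a, intervals("chr2", 10, 20)), 0L)
  # reference worked example: target peak inside the target-gene locus
  peak <- intervals("chr16", 19884686, 19885185)
  locus <- intervals("chr16", 19856691, 19886167)
  expect_gt(overlap_bp(peak, locus), 0)
  expect_equal(overlap_bp(peak, locus), overlap_bp(locus, peak))
})

test_that("overlap is symmetric, non-negative, and equals length on self", {
  set.seed(11)
  a <- rand_intervals(200)
  b <- rand_intervals(200)
  expect_identical(overlap_bp(a, b), overlap_bp(b, a))
  expect_true(all(overlap_bp(a, b) >= 0))
  expect_equal(overlap_bp(a, a), as.integer(a$end - a$start + 1))
})

test_that("malformed intervals are rejected", {
  expect_error(intervals("chr1", 20, 10), "start > end")
  expect_error(intervals("chr1", 0, 10), "1-based")
  expect_error(intervals("chr1", 1.5, 10), "whole numbers")
})

test_that("signed TSS distance follows the transcription-direction convention", {
  gplus <- gene_models("g1", "chr1", 1000, 5000, "+")
  expect_equal(distance_to_tss(intervals("chr1", 980, 1020), gplus), 0)
  expect_equal(distance_to_tss(intervals("chr1", 1500, 1600), gplus), 500)
  expect_equal(distance_to_tss(intervals("chr1", 100, 900), gplus), -100)
  # minus-strand worked example: peak ends 982 bp below the TSS, i.e. on the
  # downstream (transcribed) side of a minus-strand gene
  gm <- gene_models("GPRC5B", "chr16", 19856691, 19886167, "-")
  d <- distance_to_tss(intervals("chr16", 19884686, 19885185), gm)
  expect_equal(abs(d), 982)
  expect_equal(d, 982)
  # different chromosome: distance undefined
  expect_true(is.na(distance_to_tss(intervals("chr2", 1, 10), gplus)))
})

test_that("midpoint distance mode measures from the peak centre", {
  g <- gene_models("g1", "chr1", 1000, 5000, "+")
  expect_equal(distance_to_tss(intervals("chr1", 1500, 1600, name = "p"),
                               g, mode = "midpoint"), 550)
  gm <- gene_models("GPRC5B", "chr16", 19856691, 19886167, "-")
  dm <- distance_to_tss(intervals("chr16", 19884686, 19885185), gm,
                        mode = "midpoint")
  expect_equal(dm, 19886167 - floor((19884686 + 19885185) / 2))
})

test_that("promoter categories follow the 1 kb / 2 kb boundaries", {
  genes <- gene_models("g1", "chr1", 100000, 120000, "+")
  near <- annotate_peaks(intervals("chr1", 99950, 100050), genes)
  expect_equal(near$category, "Promoter (<=1kb)")
  mid <- annotate_peaks(intervals("chr1", 98000, 98500), genes)  # d = -1500
  expect_equal(mid$distance_to_tss, -1500)
  expect_equal(mid$category, "Promoter (1-2kb)")
  far <- annotate_peaks(intervals("chr1", 90000, 90500), genes)
  expect_equal(far$category, "Other")
  expect_error(annotate_peaks(intervals("chr1", 1, 2), genes[0, ]),
               "empty gene table")
})

test_that("annotation equals the exhaustive all-pairs oracle", {
  set.seed(42)
  peaks <- rand_intervals(150, max_pos = 3e5)
  genes <- rand_genes(60, max_pos = 3e5)
  got <- annotate_peaks(peaks, genes)
  want <- oracle_annotate(peaks, genes)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$distance_to_tss, want$distance_to_tss)
  expect_equal(got$category, want$category)
  # assigned distance is minimal in absolute value over all genes
  for (i in sample(nrow(peaks), 20)) {
    all_d <- abs(distance_to_tss(peaks[rep(i, nrow(genes)), ], genes))
    expect_equal(abs(got$distance_to_tss[i]), min(all_d, na.rm = TRUE))
  }
})

test_that("annotation is invariant under gene-list permutation", {
  set.seed(43)
  peaks <- rand_intervals(80, max_pos = 2e5)
  genes <- rand_genes(40, max_pos = 2e5)
  a1 <- annotate_peaks(peaks, genes)
  a2 <- annotate_peaks(peaks, genes[sample(nrow(genes)), ])
  expect_equal(a1, a2)
})

test_that("promoter filter preserves order and matches a direct re-filter", {
  ann <- data.frame(
    peak_id = sprintf("p%d", 1:10),
    gene_id = "g",
    distance_to_tss = c(0, 2500, -1500, 3000, 900, -999, 5000, 1800, 2100, 50),
    category = c("Promoter (<=1kb)", "Other", "Promoter (1-2kb)", "Other",
                 "Promoter (<=1kb)", "Promoter (<=1kb)", "Other",
                 "Promoter (1-2kb)", "Other", "Promoter (<=1kb)"),
    stringsAsFactors = FALSE)
  kept <- promoter_peaks(ann)
  expect_equal(kept$peak_id, ann$peak_id[ann$category != "Other"])
  expect_equal(nrow(promoter_peaks(ann[ann$category == "Other", ])), 0)
  set.seed(9)
  genes <- rand_genes(30)
  rnd <- annotate_peaks(rand_intervals(100), genes)
  expect_equal(promoter_peaks(rnd)$peak_id,
               rnd$peak_id[rnd$category %in%
                             c("Promoter (<=1kb)", "Promoter (1-2kb)")])
})
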