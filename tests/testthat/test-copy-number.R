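test_that("absolute copy number follows the purity-corrected formula", {
  # diploid identity: purity cancels at l = 0
  for (p in seq(0.1, 1, by = 0.1))
    expect_equal(absoluteCopyNumber(0, p), 2)
  expect_equal(absoluteCopyNumber(1, 0.5), 6)
  expect_equal(absoluteCopyNumber(-1, 0.8), 0.75)
  expect_error(absoluteCopyNumber(0, 0), "purity")
  expect_error(absoluteCopyNumber(0, 1.2), "purity")
})

test_that("ACN is monotone in l, and in p for deletions", {
  ls <- seq(-2, 2, by = 0.1)
  for (p in c(0.2, 0.6, 1))
    expect_true(all(diff(absoluteCopyNumber(ls, p)) > 0))
  # at fixed l < 0 the inferred deletion is deepest at low purity: the
  # same depressed ratio from a small tumor fraction implies near-total
  # loss, so ACN increases strictly with p
  ps <- seq(0.1, 1, by = 0.05)
  for (l in c(-1.5, -0.5, -0.1))
    expect_true(all(diff(absoluteCopyNumber(l, ps)) > 0))
  expect_lt(absoluteCopyNumber(-1, 0.5), absoluteCopyNumber(-1, 1))
})

test_that("weighted gene log2 is the overlap-weighted mean", {
  seg <- data.frame(chrom = "1", start = c(1, 2001), end = c(2000, 5000),
                    log2_ratio = c(1, 0))
  # 1000 bp at 1.0 and 3000 bp at 0.0
  expect_equal(weightedGeneLog2(seg, list(chrom = "1", start = 1001,
                                          end = 5000)), 0.25)
  # single spanning segment is an identity
  one <- data.frame(chrom = "1", start = 1, end = 1e6, log2_ratio = 0.5)
  expect_equal(weightedGeneLog2(one, list(chrom = "1", start = 100,
                                          end = 200)), 0.5)
  # no overlapping segment: missing with a diagnostic
  expect_message(
    res <- weightedGeneLog2(seg, list(chrom = "2", start = 1, end = 10)),
    "uncallable")
  expect_true(is.na(res))
})

test_that("weighted gene log2 is invariant to splitting segments", {
  gene <- list(chrom = "1", start = 500, end = 9500)
  whole <- data.frame(chrom = "1", start = c(1, 4001), end = c(4000, 10000),
                      log2_ratio = c(0.8, -0.3))
  cut <- data.frame(chrom = "1",
                    start = c(1, 1501, 4001, 7001, 9001),
                    end = c(1500, 4000, 7000, 9000, 10000),
                    log2_ratio = c(0.8, 0.8, -0.3, -0.3, -0.3))
  expect_equal(weightedGeneLog2(cut, gene), weightedGeneLog2(whole, gene))
})

test_that("ACN categories use the default thresholds with boundaries on the lower-severity side", {
  expect_equal(classifyAcn(2), "neutral")
  expect_equal(classifyAcn(0.2), "homozygous-deletion")
  expect_equal(classifyAcn(7.5), "high-amplification")
  expect_equal(classifyAcn(c(0.5, 1.5, 2.5, 6.0)),
               c("heterozygous-deletion", "neutral", "neutral", "gain"))
  expect_error(classifyAcn(2, thresholds = c(a = 1, b = 0.5, c = 2, d = 6)),
               "increasing")
})

test_that("acnCallTable agrees with the per-gene route and reports raw negatives", {
  gi <- defaultGeneIntervals()
  set.seed(11)
  segs <- simulateSegments(c(STK11 = 6, B2M = 0.5, CDKN2A = 0), 0.5, 0.1, gi)
  tab <- acnCallTable(segs, 0.5, gi)
  for (i in seq_len(nrow(gi))) {
    l <- suppressMessages(weightedGeneLog2(segs, gi[i, ]))
    expect_equal(tab$l[i], l, tolerance = 1e-12)
    expect_equal(tab$acn_raw[i], absoluteCopyNumber(l, 0.5))
  }
  expect_true(all(tab$acn >= 0))
  expect_true(all(tab$acn == pmax(tab$acn_raw, 0)))
})

test_that("planted ACN round-trips exactly at zero noise", {
  gi <- defaultGeneIntervals()
  genes <- gi$gene
  for (p in c(0.2, 0.5, 1.0)) {
    truth <- stats::setNames(c(0.5, 1, 2, 4, 8)[seq_along(genes) %% 5 + 1],
                             genes)
    segs <- simulateSegments(truth, p, 0, gi)
    tab <- acnCallTable(segs, p, gi)
    expect_equal(tab$acn_raw, unname(truth[tab$gene]), tolerance = 1e-9)
  }
  # infeasible inversion: ACN 0 at purity 1 has no finite log2 ratio
  expect_error(simulateSegments(c(STK11 = 0), 1.0, 0, gi), "infeasible")
})

test_that("arm-level aneuploidy counts gained and lost arms under the coverage rule", {
  arms <- defaultArmIntervals()
  # flat genome
  flat <- data.frame(chrom = paste0("chr", 1:22), start = 1, end = 5e7,
                     log2_ratio = 0)
  expect_equal(aneuploidyScore(flat, arms)$score, 0L)
  # one fully covered arm at +0.6, one at -0.6
  segs <- data.frame(chrom = c("chr8", "chr8", "chr9"),
                     start = c(1, 45600001, 49000001),
                     end = c(45600000, 146364022, 141213431),
                     log2_ratio = c(0, 0.6, -0.6))
  res <- aneuploidyScore(segs, arms)
  expect_equal(res$score, 2L)
  calls <- res$arm_calls
  expect_equal(calls$call[calls$arm == "8q"], "gain")
  expect_equal(calls$call[calls$arm == "9q"], "loss")
  expect_equal(calls$call[calls$arm == "8p"], "neutral")
  # an arm covered at only 50% stays uncalled regardless of amplitude
  half <- data.frame(chrom = "chr8", start = 45600001, end = 96000000,
                     log2_ratio = 3)
  resHalf <- aneuploidyScore(half, arms)
  expect_equal(resHalf$arm_calls$call[resHalf$arm_calls$arm == "8q"],
               "uncalled")
  # empty segment set warns and scores 0
  expect_warning(res0 <- aneuploidyScore(flat[0, ], arms), "empty")
  expect_equal(res0$score, 0L)
  expect_true(all(res0$arm_calls$call == "uncalled"))
})
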