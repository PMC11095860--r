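test_that("probability-1 and probability-0 planting are exact", {
  key <- eventKey("STK11", "SNV", "p.K78fs")
  cfgAll <- SimConfig(nPatients = 10L,
                      acquiredEventFreqs = stats::setNames(1.0, key),
                      baselineEventFreqs = numeric(0), biallelicFreq = 0,
                      segmentNoiseSd = 0, seed = 11L)
  simAll <- simulateCohort(cfgAll, nSpatial = 0L)
  for (case in simAll$cases) {
    expect_true(key %in% variants(postSample(case))$event_key)
    expect_false(key %in% variants(preSample(case))$event_key)
  }
  cfgNone <- SimConfig(nPatients = 10L,
                       acquiredEventFreqs = stats::setNames(0, key),
                       baselineEventFreqs = numeric(0), biallelicFreq = 0,
                       segmentNoiseSd = 0, seed = 11L)
  simNone <- simulateCohort(cfgNone, nSpatial = 0L)
  expect_true(all(lengths(simNone$groundTruth$plantedAcquired) == 0))
  for (case in simNone$cases)
    expect_equal(nrow(callAcquired(case)$findings), 0)
})

test_that("baseline and private events appear in both samples of a pair", {
  cfg <- SimConfig(nPatients = 6L, seed = 21L)
  sim <- simulateCohort(cfg, nSpatial = 0L)
  for (case in sim$cases) {
    preKeys <- variants(preSample(case))$event_key
    postKeys <- variants(postSample(case))$event_key
    expect_true(all(preKeys %in% postKeys))
    planted <- sim$groundTruth$plantedAcquired[[patientId(case)]]
    mutPlanted <- planted[!grepl("gene-CNA", planted)]
    expect_true(all(mutPlanted %in% postKeys))
    expect_false(any(mutPlanted %in% preKeys))
  }
})

test_that("identical config and seed reproduce identical output", {
  cfg <- SimConfig(nPatients = 5L, seed = 33L)
  s1 <- simulateCohort(cfg, nSpatial = 2L)
  s2 <- simulateCohort(cfg, nSpatial = 2L)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$hscores, s2$hscores)
  expect_identical(lapply(s1$cellFrames, cells),
                   lapply(s2$cellFrames, cells))
  d1 <- tempfile(); d2 <- tempfile()
  writeSimOutputs(s1, d1); writeSimOutputs(s2, d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("segment simulation inverts the ACN formula", {
  gi <- defaultGeneIntervals()
  # ACN 2 at any purity: log2 ratio 0 everywhere
  segs <- simulateSegments(c(STK11 = 2), 0.37, 0, gi)
  expect_true(all(segs$log2_ratio == 0))
  # ACN 6 at purity 0.5: gene segment log2 ratio exactly 1
  segs6 <- simulateSegments(c(STK11 = 6), 0.5, 0, gi)
  g <- gi[gi$gene == "STK11", ]
  geneSeg <- segs6[segs6$chrom == g$chrom & segs6$start == g$start, ]
  expect_equal(geneSeg$log2_ratio, 1.0)
  expect_error(simulateSegments(c(STK11 = 0), 1.0, 0, gi), "infeasible")
  expect_error(simulateSegments(c(STK11 = -1), 0.5, 0, gi), ">= 0")
  expect_error(simulateSegments(c(STK11 = 2), 0, 0, gi), "purity")
})

test_that("cell placement hits the planted engagement and Poisson densities", {
  sp <- list(areaMm2 = 1, density = c(lymphocyte = 100, PD1 = 50, PDL1 = 60),
             targetEngagement = 0.3)
  sim <- simulateCells(sp, seed = 41L)
  ef <- engagementFraction(sim$frame)
  expect_identical(ef$fraction, sim$achievedEngagement)
  # lymphocyte count within the Poisson(100) 99% interval
  nLym <- sum(cells(sim$frame)$cell_class == "lymphocyte" &
                !cells(sim$frame)$PD1)
  expect_gte(nLym, qpois(0.005, 100))
  expect_lte(nLym, qpois(0.995, 100))
  # target 0 gives exactly 0, target 1 gives exactly 1
  sp0 <- sp; sp0$targetEngagement <- 0
  e0 <- engagementFraction(simulateCells(sp0, seed = 42L)$frame)
  expect_identical(e0$fraction, 0)
  sp1 <- sp; sp1$targetEngagement <- 1
  e1 <- engagementFraction(simulateCells(sp1, seed = 43L)$frame)
  expect_identical(e1$fraction, 1)
  sp$targetEngagement <- 1.2
  expect_error(simulateCells(sp, seed = 1L), "targetEngagement")
})

test_that("invalid simulator configurations are rejected", {
  expect_error(SimConfig(nPatients = 5L, therapyMix = c("ICI-mono" = 0.7)),
               "sum to 1")
  expect_error(SimConfig(nPatients = 5L, therapyMix = numeric(0)),
               "non-empty")
  expect_error(SimConfig(nPatients = 5L, purityRange = c(0, 0.9)),
               "purityRange")
  expect_error(SimConfig(nPatients = 5L,
                         acquiredEventFreqs = c("STK11|SNV|p.K78fs" = 1.4)),
               "\\[0, 1\\]")
})

test_that("planted biallelic events produce concurrent mutation and loss", {
  key <- eventKey("B2M", "SNV", "p.E94*")
  cfg <- SimConfig(nPatients = 12L,
                   acquiredEventFreqs = stats::setNames(1.0, key),
                   baselineEventFreqs = numeric(0), biallelicFreq = 1,
                   segmentNoiseSd = 0, seed = 55L)
  sim <- simulateCohort(cfg, nSpatial = 0L)
  for (case in sim$cases) {
    f <- callAcquired(case)$findings
    b2m <- f[f$gene == "B2M", ]
    expect_setequal(b2m$finding_type, c("mutation", "heterozygous-loss"))
    expect_true(all(b2m$biallelic))
  }
})
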