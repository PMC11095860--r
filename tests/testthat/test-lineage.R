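test_that("catalog frequencies are per-sample presence fractions", {
  ev <- c("TP53|SNV|p.R273H", "KRAS|SNV|p.G12C")
  samples <- c(lapply(1:3, function(i) ev), lapply(4:10, function(i) ev[1]))
  names(samples) <- paste0("s", 1:10)
  cat <- buildCatalog(samples)
  expect_equal(cohortSize(cat), 10L)
  expect_equal(unname(eventFreq(cat)[ev[1]]), 1.0)   # saturation
  expect_equal(unname(eventFreq(cat)[ev[2]]), 0.3)   # 3 of 10
  expect_error(buildCatalog(list()), "empty")
  # one-sample-per-patient counting
  catPre <- buildCatalog(samples, countSamples = c("s1", "s4"))
  expect_equal(cohortSize(catPre), 2L)
  expect_equal(unname(eventFreq(catPre)[ev[2]]), 0.5)
})

test_that("similarity score matches hand evaluations of the formula", {
  cat10 <- new("EventCatalog", cohortSize = 10L,
               freq = c("TP53|SNV|p.R273H" = 0.1))
  # empty pair: empty product
  expect_equal(similarity(similarityScore(character(0), character(0), cat10)), 0)
  # one shared event, f = 0.1, alpha = 1: -ln(0.01)
  r <- similarityScore("TP53|SNV|p.R273H", "TP53|SNV|p.R273H", cat10)
  expect_equal(similarity(r), -log(0.01), tolerance = 1e-12)
  expect_equal(sharedEvents(r), "TP53|SNV|p.R273H")
  # one unshared event: -ln(1 - 0.01)
  expect_equal(similarity(similarityScore("TP53|SNV|p.R273H", character(0),
                                          cat10)),
               -log(0.99), tolerance = 1e-12)
  expect_error(similarityScore("x", "x", cat10, alpha = 0), "alpha")
  expect_error(similarityScore("x", "x", cat10, alpha = -1), "alpha")
})

test_that("an unshared ubiquitous event yields +Inf with a flag, not a crash", {
  catSat <- new("EventCatalog", cohortSize = 5L, freq = c("A|SNV|p.X1Y" = 1))
  expect_warning(r <- similarityScore("A|SNV|p.X1Y", character(0), catSat),
                 "frequency 1")
  expect_true(is.infinite(similarity(r)))
  expect_true(r@flagged)
})

test_that("events absent from the catalog are imputed f = 1/(N+1)", {
  cat10 <- new("EventCatalog", cohortSize = 10L,
               freq = c("TP53|SNV|p.R273H" = 0.1))
  expect_message(r <- similarityScore("NEW|SNV|p.Q1P", "NEW|SNV|p.Q1P", cat10),
                 "imputing")
  expect_equal(similarity(r), -log((1 / 11)^2), tolerance = 1e-12)
})

test_that("score is symmetric, additive over disjoint universes, and matches the brute-force oracle", {
  set.seed(101)
  for (i in 1:100) {
    inst <- randomSimilarityInstance()
    alpha <- sample(c(0.5, 1, 2), 1)
    r1 <- similarityScore(inst$a, inst$b, inst$catalog, alpha = alpha)
    r2 <- similarityScore(inst$b, inst$a, inst$catalog, alpha = alpha)
    expect_identical(similarity(r1), similarity(r2))
    expect_equal(similarity(r1),
                 bruteSimilarity(inst$a, inst$b, inst$freq, alpha),
                 tolerance = 1e-12)
    # score equals the sum of reported contributions
    expect_equal(similarity(r1), sum(contributions(r1)), tolerance = 1e-9)
    # nonnegativity at alpha <= 1
    if (alpha <= 1) expect_true(all(contributions(r1) >= 0))
  }
  # additivity over disjoint event universes
  i1 <- randomSimilarityInstance()
  freq2 <- stats::setNames(c(0.2, 0.4), c("H1|SNV|p.A1B", "H2|SNV|p.C2D"))
  cat12 <- new("EventCatalog", cohortSize = 100L, freq = c(i1$freq, freq2))
  a2 <- "H1|SNV|p.A1B"; b2 <- c("H1|SNV|p.A1B", "H2|SNV|p.C2D")
  whole <- similarity(similarityScore(c(i1$a, a2), c(i1$b, b2), cat12))
  part1 <- similarity(similarityScore(i1$a, i1$b, cat12))
  part2 <- similarity(similarityScore(a2, b2, cat12))
  expect_equal(whole, part1 + part2, tolerance = 1e-9)
})

test_that("shared-event contribution decreases with frequency", {
  fs <- seq(0.05, 1, by = 0.05)
  contr <- vapply(fs, function(f) {
    cat1 <- new("EventCatalog", cohortSize = 100L, freq = c("G|SNV|p.X1Y" = f))
    similarity(similarityScore("G|SNV|p.X1Y", "G|SNV|p.X1Y", cat1))
  }, numeric(1))
  expect_true(all(diff(contr) < 0))
})

test_that("permutation null is deterministic and supports lineage calls", {
  set.seed(5)
  samples <- list()
  patientOf <- character(0)
  for (i in 1:8) {
    keys <- sprintf("C%d|SNV|p.N%dK", sample(1:6, 3), 1:3)
    samples[[paste0("p", i, "_pre")]] <- keys
    samples[[paste0("p", i, "_post")]] <- keys
    patientOf[paste0("p", i, "_pre")] <- paste0("p", i)
    patientOf[paste0("p", i, "_post")] <- paste0("p", i)
  }
  cat8 <- buildCatalog(samples, countSamples = grep("_pre", names(samples),
                                                    value = TRUE))
  n1 <- calibrateNull(cat8, samples, patientOf, nPermutations = 200L,
                      seed = 9L)
  n2 <- calibrateNull(cat8, samples, patientOf, nPermutations = 200L,
                      seed = 9L)
  expect_identical(n1$scores, n2$scores)
  expect_warning(calibrateNull(cat8, samples, patientOf,
                               nPermutations = 50L, seed = 1L), "100")
  onePat <- samples[1:2]
  expect_error(calibrateNull(cat8, onePat, patientOf[1:2]), "2 distinct")
  # threshold percentile 100: nothing is ever called shared-lineage
  r <- similarityScore(samples[[1]], samples[[2]], cat8)
  r100 <- sharedLineageCall(r, n1, percentile = 100)
  expect_false(r100@sharedLineageCall)
  expect_error(sharedLineageCall(r, n1, percentile = 101), "percentile")
})
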