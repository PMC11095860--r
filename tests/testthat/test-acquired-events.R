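test_that("benign and CHIP variants are removed before calling", {
  v <- rbind(mutRow("STK11"), mutRow("B2M"), mutRow("APC"), mutRow("KRAS"))
  v$benign <- c(TRUE, FALSE, TRUE, FALSE)
  v$chip <- c(FALSE, TRUE, FALSE, FALSE)
  expect_message(out <- filterVariants(v), "filtered 2 benign and 1 CHIP")
  expect_equal(out$gene, "KRAS")
  # identity when all flags are false
  clean <- rbind(mutRow("STK11"), mutRow("B2M"))
  expect_identical(filterVariants(clean), clean)
  # absent flag columns are treated as FALSE with a message
  noflags <- clean[, setdiff(names(clean), c("benign", "chip"))]
  expect_message(out2 <- filterVariants(noflags), "absent")
  expect_equal(nrow(out2), 2)
})

test_that("acquired calls require post-only presence", {
  # identical mutation pre and post: nothing acquired
  same <- toyPair("p1", baseMut = "STK11")
  expect_equal(nrow(callAcquired(same)$findings), 0)
  # pre-empty pair acquiring B2M mutation + heterozygous loss: biallelic
  bi <- toyPair("p2", acqMut = "B2M", acqMutDetail = "p.E94*",
                acqCna = "B2M")
  f <- callAcquired(bi)$findings
  expect_equal(nrow(f), 2)
  expect_setequal(f$finding_type, c("mutation", "heterozygous-loss"))
  expect_true(all(f$biallelic))
  # neutral -> high amplification
  amp <- toyPair("p3", acqCna = "KRAS", acqCnaCat = "high-amplification")
  f <- callAcquired(amp)$findings
  expect_equal(f$finding_type, "amplification")
  expect_equal(f$gene, "KRAS")
})

test_that("reversions are reported separately and never as acquired", {
  pre <- SampleProfile("p4_pre", "pre", variants = mutRow("KEAP1"),
                       acnCalls = acnTable("STK11", "homozygous-deletion"))
  post <- SampleProfile("p4_post", "post",
                        acnCalls = acnTable("STK11", "heterozygous-deletion"))
  pair <- PairedCase("p4", pre, post)
  res <- callAcquired(pair)
  expect_equal(nrow(res$findings), 0)  # hom -> het is a move toward neutral
  expect_equal(res$lost$gene, "KEAP1")
})

test_that("deeper same-direction CNA changes qualify as acquired", {
  pair <- PairedCase("p5",
    SampleProfile("p5_pre", "pre",
                  acnCalls = acnTable("CDKN2A", "heterozygous-deletion")),
    SampleProfile("p5_post", "post",
                  acnCalls = acnTable("CDKN2A", "homozygous-deletion")))
  f <- callAcquired(pair)$findings
  expect_equal(f$finding_type, "homozygous-deletion")
})

test_that("adding a post event never removes an existing finding", {
  base <- toyPair("p6", acqMut = "STK11")
  f0 <- callAcquired(base)$findings
  grown <- toyPair("p6", acqMut = c("STK11", "JAK1"))
  f1 <- callAcquired(grown)$findings
  expect_true(all(f0$event %in% f1$event))
})

test_that("cohort summary keeps denominator discipline", {
  cases <- toyCohort79()[1:30]
  s <- summarizeCohort(cases)
  expect_true(all(s$overall$denominator == 30))
  anyPct <- s$overall$pct[s$overall$measure == "any_change"]
  expect_true(anyPct >= max(s$overall$pct[s$overall$measure != "any_change"]))
  expect_error(summarizeCohort(list()), "empty")
  # per-gene counts deduplicate patients within a finding type
  expect_true(all(s$per_gene$n_patients <= 30))
})

test_that("stratification runs exact Fisher tests on two-stratum splits", {
  # identical event rates in both strata: p = 1
  cases <- c(lapply(1:10, function(i)
               toyPair(paste0("a", i), acqMut = if (i <= 5) "STK11"
                                                else character(0),
                       timeToAR = 4)),
             lapply(1:10, function(i)
               toyPair(paste0("b", i), acqMut = if (i <= 5) "STK11"
                                                else character(0),
                       timeToAR = 12)))
  res <- stratifyCohort(cases, by = "time_to_ar", cutoffMonths = 6)
  expect_equal(res$tests$p_value[res$tests$measure == "acquired_mutation"], 1)
  # 5/10 vs 0/10: p from the hypergeometric enumeration oracle
  skew <- c(lapply(1:10, function(i)
              toyPair(paste0("c", i), acqMut = if (i <= 5) "STK11"
                                               else character(0),
                      timeToAR = 4)),
            lapply(1:10, function(i)
              toyPair(paste0("d", i), timeToAR = 12)))
  res2 <- stratifyCohort(skew, by = "time_to_ar", cutoffMonths = 6)
  p <- res2$tests$p_value[res2$tests$measure == "acquired_mutation"]
  expect_equal(p, bruteFisher(5, 5, 0, 10), tolerance = 1e-12)
  # a cutoff isolating an empty stratum drops it (with all pairs on one
  # side there is nothing to test)
  res3 <- stratifyCohort(skew[1:10], by = "time_to_ar", cutoffMonths = 6)
  expect_equal(length(res3$strata), 1L)
  expect_null(res3$tests)
})

test_that("oncoprint matrix codes one cell per gene and patient", {
  cases <- list(toyPair("m1", acqMut = "STK11", acqCna = "STK11"),
                toyPair("m2", acqMut = "B2M"))
  m <- acquiredMatrix(cases)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["STK11", "m1"], "heterozygous-loss;mutation")
  expect_equal(m["B2M", "m2"], "mutation")
  expect_equal(m["B2M", "m1"], "")
})
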