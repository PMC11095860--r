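mkFrame <- function(df, area = 1) {
  df$cell_id <- as.character(seq_len(nrow(df)))
  CellFrame(df, tissueAreaMm2 = area)
}

test_that("radius search is inclusive at the boundary and excludes self-pairs", {
  fr <- mkFrame(data.frame(x = c(0, 12), y = c(0, 16),
                           PD1 = TRUE, PDL1 = TRUE))
  # 3-4-5 triangle scaled: distance exactly 20
  nb <- neighborsWithin(fr, "PDL1", "PD1", 20)
  expect_equal(nb[["1"]]$cell_id, "2")
  expect_equal(nb[["1"]]$distance, 20)
  expect_equal(nb[["2"]]$cell_id, "1")
  # double-positive cells never pair with themselves
  expect_false("1" %in% nb[["1"]]$cell_id)
  # no target-marker cells: every query maps to an empty set
  fr2 <- mkFrame(data.frame(x = c(0, 5), y = c(0, 5), PD1 = FALSE,
                            PDL1 = TRUE))
  nb2 <- neighborsWithin(fr2, "PDL1", "PD1", 20)
  expect_true(all(vapply(nb2, nrow, integer(1)) == 0))
  expect_error(neighborsWithin(fr, "PDL1", "PD1", 0), "radiusUm")
})

test_that("grid-indexed neighbor search equals the all-pairs oracle", {
  set.seed(73)
  for (rep in 1:25) {
    n <- sample(50:600, 1)
    df <- data.frame(x = runif(n, -200, 800), y = runif(n, -200, 800),
                     PD1 = runif(n) < 0.3, PDL1 = runif(n) < 0.3)
    fr <- mkFrame(df)
    radius <- sample(c(10, 20, 35), 1)
    nb <- neighborsWithin(fr, "PDL1", "PD1", radius)
    want <- bruteNeighbors(cells(fr), which(df$PDL1), which(df$PD1), radius)
    for (j in seq_along(nb)) {
      expect_setequal(nb[[j]]$cell_id, as.character(want[[j]]$idx))
      expect_equal(sort(nb[[j]]$distance), sort(want[[j]]$distance),
                   tolerance = 1e-12)
    }
  }
})

test_that("nearest-neighbor distances equal the brute-force minimum", {
  set.seed(79)
  for (rep in 1:15) {
    n <- sample(50:400, 1)
    df <- data.frame(x = runif(n, 0, 500), y = runif(n, 0, 500),
                     CK = runif(n) < 0.5, CD8a = runif(n) < 0.4,
                     PD1 = runif(n) < 0.4)
    df$CK[1] <- TRUE
    fr <- mkFrame(df)
    res <- suppressWarnings(nearestDistance(fr))
    fromIdx <- which(df$CK)
    toIdx <- which(df$CD8a & df$PD1)
    for (j in seq_along(fromIdx)) {
      i <- fromIdx[j]
      tset <- setdiff(toIdx, i)
      want <- if (length(tset))
        min(sqrt((df$x[tset] - df$x[i])^2 + (df$y[tset] - df$y[i])^2))
        else NA_real_
      expect_equal(res$distances$distance[j], want, tolerance = 1e-12)
    }
  }
  # simple 3-4-5 case
  fr <- mkFrame(data.frame(x = c(0, 3), y = c(0, 4), CK = c(TRUE, FALSE),
                           CD8a = c(FALSE, TRUE), PD1 = c(FALSE, TRUE)))
  expect_equal(nearestDistance(fr)$median, 5)
  # empty to-set: missing distances with a warning
  fr0 <- mkFrame(data.frame(x = c(0, 3), y = c(0, 4), CK = TRUE,
                            CD8a = FALSE, PD1 = FALSE))
  expect_warning(r0 <- nearestDistance(fr0), "missing")
  expect_true(all(is.na(r0$distances$distance)))
  expect_equal(r0$n_missing, 2L)
})

test_that("engagement counts PD-L1+ cells with an in-radius PD-1+ neighbor", {
  fr <- mkFrame(data.frame(x = c(0, 5), y = c(0, 0),
                           PDL1 = c(TRUE, FALSE), PD1 = c(FALSE, TRUE)))
  expect_equal(engagementFraction(fr)$fraction, 1)
  # 4 PD-L1+ cells, only one with a PD-1+ cell inside the radius
  fr4 <- mkFrame(data.frame(
    x = c(0, 100, 200, 300, 10), y = 0,
    PDL1 = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    PD1 = c(FALSE, FALSE, FALSE, FALSE, TRUE)))
  e <- engagementFraction(fr4)
  expect_equal(e$fraction, 0.25)
  expect_equal(e$n_pdl1, 4L)
  expect_equal(e$n_interactors, 1L)
  # no PD-L1+ cells: undefined, never 0
  fr0 <- mkFrame(data.frame(x = 1, y = 1, PDL1 = FALSE, PD1 = TRUE))
  expect_message(e0 <- engagementFraction(fr0), "undefined")
  expect_true(is.na(e0$fraction))
})

test_that("removing a PD-1+ cell never increases engagement", {
  set.seed(83)
  df <- data.frame(x = runif(120, 0, 300), y = runif(120, 0, 300),
                   PDL1 = runif(120) < 0.4, PD1 = runif(120) < 0.4)
  fr <- mkFrame(df)
  base <- engagementFraction(fr)$fraction
  for (drop in which(df$PD1)[1:5]) {
    df2 <- df
    df2$PD1[drop] <- FALSE
    expect_lte(engagementFraction(mkFrame(df2))$fraction, base)
  }
})

test_that("spatial metrics are invariant under translation and rotation", {
  set.seed(89)
  df <- data.frame(x = runif(150, 0, 400), y = runif(150, 0, 400),
                   PDL1 = runif(150) < 0.3, PD1 = runif(150) < 0.3,
                   CK = runif(150) < 0.4, CD8a = runif(150) < 0.3)
  fr <- mkFrame(df)
  theta <- 0.7
  rot <- df
  rot$x <- cos(theta) * df$x - sin(theta) * df$y + 1234.5
  rot$y <- sin(theta) * df$x + cos(theta) * df$y - 987.6
  frRot <- mkFrame(rot)
  expect_equal(engagementFraction(frRot)$fraction,
               engagementFraction(fr)$fraction, tolerance = 1e-9)
  d1 <- suppressWarnings(nearestDistance(fr))$distances$distance
  d2 <- suppressWarnings(nearestDistance(frRot))$distances$distance
  expect_equal(d2, d1, tolerance = 1e-9)
})

test_that("density is count over area and scales linearly with area", {
  df <- data.frame(x = runif(100), y = runif(100), cell_class = "lymphocyte",
                   PD1 = FALSE)
  expect_equal(cellDensity(mkFrame(df, area = 1), "class:lymphocyte"), 100)
  expect_equal(cellDensity(mkFrame(df, area = 2), "class:lymphocyte"), 50)
  expect_equal(cellDensity(mkFrame(df, area = 1), "PD1"), 0)
  # a 36-cell frame over 1 mm^2 gives exactly 36 cells/mm^2
  expect_equal(cellDensity(mkFrame(df[1:36, ], area = 1),
                           "class:lymphocyte"), 36)
})
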