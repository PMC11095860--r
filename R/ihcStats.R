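#' Immunohistochemistry H-score
#'
#' Standard H-score from the percentage of cells at staining intensity
#' 0-3: `1*pct1 + 2*pct2 + 3*pct3`, range 0 (all negative) to 300 (all at
#' intensity 3).
#'
#' @param pct0,pct1,pct2,pct3 Percentages of cells at each intensity; must
#'   sum to 100 (tolerance 1e-6).
#' @return H-score in \[0, 300\].
#' @examples
#' hScore(20, 0, 50, 30)  # 190
#' @export
hScore <- function(pct0, pct1, pct2, pct3) {
  p <- c(pct0, pct1, pct2, pct3)
  if (any(p < 0) || any(p > 100))
    stop("intensity percentages must lie in [0, 100]")
  if (abs(sum(p) - 100) > 1e-6)
    stop("intensity percentages must sum to 100, got ", sum(p))
  1 * pct1 + 2 * pct2 + 3 * pct3
}

#' Absolute and percent change in a paired score
#'
#' Percent change from a zero baseline is undefined and reported missing
#' (never infinite): a marker absent pre-treatment has no meaningful
#' relative change.
#'
#' @param pre,post Paired scores (vectorized).
#' @return data.frame with columns `absolute` (post - pre) and `percent`
#'   (100 * (post - pre) / pre, `NA` where pre = 0).
#' @examples
#' deltaH(190, 0)   # absolute -190, percent -100
#' deltaH(0, 40)    # absolute 40, percent NA
#' @export
deltaH <- function(pre, post) {
  absolute <- post - pre
  percent <- ifelse(pre == 0, NA_real_, 100 * absolute / pre)
  data.frame(absolute = absolute, percent = percent)
}

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments on the (tie-averaged) ranks of |d|. Null is symmetric about
# mu = sum(ranks)/2, so the two-sided p is the mass at deviations >= the
# observed one.
.wilcoxonEnumerate <- function(ranks, wObs) {
  n <- length(ranks)
  mu <- sum(ranks) / 2
  # distribution of W+ over all sign assignments via convolution on a
  # half-unit lattice (average ranks can be x.5)
  r2 <- as.integer(round(2 * ranks))
  maxS <- sum(r2)
  dist <- numeric(maxS + 1L)  # counts for W+*2 = 0..maxS
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(maxS + 1L - r)])
    dist <- dist + shifted
  }
  dev <- abs(seq(0L, maxS) / 2 - mu)
  obsDev <- abs(wObs - mu)
  sum(dist[dev >= obsDev - 1e-9]) / 2^n
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for a difference in paired observations,
#' exact by full enumeration of all 2^n sign assignments for n <= 25 pairs
#' (after zero-difference handling), with average ranks for tied absolute
#' differences; a continuity-corrected normal approximation is used above.
#' With six untied pairs all shifting the same direction the exact p is
#' 2/64 = 0.03125.
#'
#' @param pre,post Paired measurements, equal length, no missing halves.
#' @param zeroPolicy `"drop"` (classic: zero differences removed before
#'   ranking) or `"pratt"` (zeros ranked, then dropped from the
#'   statistic).
#' @param exactLimit Largest n for the enumeration branch (default 25).
#' @return List with `p.value`, `statistic` (W+, sum of positive-signed
#'   ranks), `n` (pairs used), `method`.
#' @examples
#' pairedWilcoxon(c(5, 7, 3, 9, 4, 6), c(1, 2, 1, 3, 2, 5))$p.value  # 0.03125
#' @export
pairedWilcoxon <- function(pre, post, zeroPolicy = c("drop", "pratt"),
                           exactLimit = 25L) {
  zeroPolicy <- match.arg(zeroPolicy)
  if (length(pre) != length(post))
    stop("pre and post must have equal length")
  if (anyNA(pre) || anyNA(post))
    stop("paired series must have no missing halves")
  if (!length(pre)) stop("need n >= 1 pairs")
  d <- post - pre
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(p.value = 1, statistic = 0, n = 0L,
                method = "degenerate (all zero differences)"))
  }
  if (zeroPolicy == "drop") {
    d <- d[d != 0]
    ranks <- rank(abs(d))
    wObs <- sum(ranks[d > 0])
  } else {
    ranks <- rank(abs(d))
    wObs <- sum(ranks[d > 0])
    ranks <- ranks[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  if (n <= exactLimit) {
    p <- .wilcoxonEnumerate(ranks, wObs)
    method <- "exact enumeration of sign assignments"
  } else {
    mu <- sum(ranks) / 2
    sigma <- sqrt(sum(ranks^2) / 4)
    z <- (abs(wObs - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation with continuity correction"
  }
  list(p.value = min(p, 1), statistic = wObs, n = n, method = method)
}

#' Exact two-sided Fisher test on a 2x2 table
#'
#' Two-sided p by the probability-ordering convention: with margins fixed,
#' sum the hypergeometric probabilities of every table whose probability
#' does not exceed (up to a relative tolerance of 1e-7) that of the
#' observed table. A table with a zero margin carries no information about
#' association: p = 1 with a warning.
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows = groups, columns
#'   = outcomes (`a` and `b` in row 1).
#' @return List with `p.value`, `odds.ratio` (sample cross-product ratio,
#'   `NA` when undefined), `table`.
#' @examples
#' fisherExact(5, 0, 0, 5)$p.value  # 2/252
#' @export
fisherExact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    warning("zero margin: association undefined, p = 1")
    return(list(p.value = 1, odds.ratio = NA_real_,
                table = matrix(counts, 2, byrow = TRUE)))
  }
  lo <- max(0, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  pObs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  list(p.value = min(p, 1), odds.ratio = or,
       table = matrix(counts, 2, byrow = TRUE))
}

#' Paired-statistics report over named measurement series
#'
#' Convenience wrapper producing the study-style report table: one row per
#' metric with n, pre/post medians, the paired Wilcoxon p and the test
#' branch used.
#'
#' @param series Named list; each element a data.frame or list with
#'   numeric `pre` and `post` of equal length.
#' @param zeroPolicy Passed to [pairedWilcoxon()].
#' @return data.frame with columns `metric`, `n`, `median_pre`,
#'   `median_post`, `p_value`, `method`.
#' @export
pairedReport <- function(series, zeroPolicy = "drop") {
  stopifnot(length(series) > 0, !is.null(names(series)))
  rows <- lapply(names(series), function(nm) {
    s <- series[[nm]]
    wt <- suppressWarnings(pairedWilcoxon(s$pre, s$post,
                                          zeroPolicy = zeroPolicy))
    data.frame(metric = nm, n = length(s$pre),
               median_pre = stats::median(s$pre),
               median_post = stats::median(s$post),
               p_value = wt$p.value, method = wt$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Continuity-corrected chi-squared test on a 2x2 table
#'
#' Large-sample fallback to [fisherExact()]; delegates to
#' [stats::chisq.test()] with Yates continuity correction.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return List with `p.value` and `statistic`.
#' @export
chisqTest2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  ht <- stats::chisq.test(m, correct = TRUE)
  list(p.value = unname(ht$p.value), statistic = unname(ht$statistic))
}
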