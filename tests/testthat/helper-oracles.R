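# Independent brute-force oracles used across the suite. These are kept
# deliberately literal (products, full enumerations, all-pairs scans) and
# share no code with the implementation paths they check.

# literal product-then-log similarity score
bruteSimilarity <- function(eventsA, eventsB, freq, alpha = 1) {
  keys <- union(eventsA, eventsB)
  prod <- 1
  for (k in keys) {
    f <- freq[[k]]
    prod <- prod * if (k %in% eventsA && k %in% eventsB) alpha * f^2
                   else 1 - f^2
  }
  -log(prod)
}

# literal 2^n enumeration of the signed-rank two-sided p
bruteWilcoxon <- function(pre, post, zeroPolicy = "drop") {
  d <- post - pre
  if (zeroPolicy == "drop") d <- d[d != 0]
  if (!length(d)) return(1)
  r <- rank(abs(d))
  n <- length(d)
  mu <- sum(r) / 2
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# full-table enumeration of the two-sided Fisher p (probability ordering)
bruteFisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  total <- 0
  pObs <- choose(m, a) * choose(n2, c) / choose(m + n2, k)
  for (x in max(0, k - n2):min(k, m)) {
    px <- choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
    if (px <= pObs * (1 + 1e-7)) total <- total + px
  }
  min(1, total)
}

# all-pairs neighbor sets within a radius (inclusive boundary)
bruteNeighbors <- function(cellsDf, queryIdx, targetIdx, radius) {
  lapply(queryIdx, function(i) {
    d <- sqrt((cellsDf$x[targetIdx] - cellsDf$x[i])^2 +
                (cellsDf$y[targetIdx] - cellsDf$y[i])^2)
    keep <- targetIdx != i & d <= radius
    data.frame(idx = targetIdx[keep], distance = d[keep])
  })
}

# random small event-set instance for similarity checks
randomSimilarityInstance <- function(maxEvents = 10) {
  nEv <- sample.int(maxEvents, 1)
  keys <- sprintf("G%d|SNV|p.X%dY", seq_len(nEv), seq_len(nEv))
  freq <- stats::setNames(round(runif(nEv, 0.05, 0.95), 3), keys)
  a <- keys[runif(nEv) < 0.5]
  b <- keys[runif(nEv) < 0.5]
  list(a = a, b = b, freq = freq,
       catalog = new("EventCatalog", cohortSize = 100L, freq = freq))
}
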