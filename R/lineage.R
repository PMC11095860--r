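#' SimilarityResult: outcome of a tumor-pair similarity comparison
#'
#' @slot score Nonnegative similarity score (may be `Inf`, see
#'   [similarityScore()]).
#' @slot sharedEvents Canonical keys of events present in both samples.
#' @slot contributions Named per-event score contributions; the score is
#'   their sum.
#' @slot nullPercentile Percentile of the score within a permutation null
#'   (0-100), or `NA` when no null was supplied.
#' @slot sharedLineageCall Logical shared-lineage call, or `NA`.
#' @slot flagged TRUE when any unshared event had cohort frequency 1
#'   (infinite contribution).
#' @export
setClass("SimilarityResult",
  representation(score = "numeric", sharedEvents = "character",
    contributions = "numeric", nullPercentile = "numeric",
    sharedLineageCall = "logical", flagged = "logical"),
  prototype(nullPercentile = NA_real_, sharedLineageCall = NA,
            flagged = FALSE)
)

setValidity("SimilarityResult", function(object) {
  s <- object@score
  tot <- sum(object@contributions)
  if (is.finite(s) && is.finite(tot) && abs(s - tot) > 1e-9)
    return("score must equal the sum of per-event contributions (tol 1e-9)")
  TRUE
})

#' @rdname SimilarityResult-class
#' @param object A SimilarityResult.
#' @export
setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult: score %.4f over %d events (%d shared)%s\n",
              object@score, length(object@contributions),
              length(object@sharedEvents),
              if (isTRUE(object@flagged)) " [flagged: f=1 unshared]" else ""))
  if (!is.na(object@nullPercentile))
    cat(sprintf("  null percentile %.1f; shared-lineage call: %s\n",
                object@nullPercentile, object@sharedLineageCall))
  invisible(NULL)
})

#' @rdname SimilarityResult-class
#' @param x A SimilarityResult.
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))
#' @rdname SimilarityResult-class
#' @export
setMethod("similarity", "SimilarityResult", function(x) x@score)
#' @rdname SimilarityResult-class
#' @export
setGeneric("sharedEvents", function(x) standardGeneric("sharedEvents"))
#' @rdname SimilarityResult-class
#' @export
setMethod("sharedEvents", "SimilarityResult", function(x) x@sharedEvents)
#' @rdname SimilarityResult-class
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))
#' @rdname SimilarityResult-class
#' @export
setMethod("contributions", "SimilarityResult", function(x) x@contributions)

#' Build a cohort event-frequency catalog
#'
#' Counts, for every canonical event key, the fraction of counted samples
#' carrying it: f_i = (samples containing event i) / N. Events never
#' observed are absent from the catalog. When a cohort contains multiple
#' samples per patient, pass `countSamples` to count one sample per
#' patient (conventionally the pre-treatment sample) so that patients with
#' two biopsies do not inflate frequencies.
#'
#' @param perSampleEvents Named list: sample id -> character vector of
#'   canonical event keys (see [eventKey()]).
#' @param countSamples Sample ids forming the frequency denominator;
#'   defaults to all samples.
#' @return An [EventCatalog].
#' @examples
#' ev <- list(s1 = "TP53|SNV|p.R273H", s2 = c("TP53|SNV|p.R273H", "KRAS|SNV|p.G12C"))
#' eventFreq(buildCatalog(ev))
#' @export
buildCatalog <- function(perSampleEvents, countSamples = names(perSampleEvents)) {
  if (!length(perSampleEvents))
    stop("empty cohort: no samples to count")
  if (!all(countSamples %in% names(perSampleEvents)))
    stop("countSamples must name samples present in perSampleEvents")
  counted <- perSampleEvents[countSamples]
  n <- length(counted)
  if (!n) stop("empty cohort: countSamples selects no samples")
  tab <- table(unlist(lapply(counted, unique)))
  freq <- as.numeric(tab) / n
  names(freq) <- names(tab)
  new("EventCatalog", cohortSize = as.integer(n), freq = freq)
}

.catalogLookup <- function(keys, catalog) {
  f <- eventFreq(catalog)[keys]
  miss <- is.na(f)
  if (any(miss)) {
    imput <- 1 / (cohortSize(catalog) + 1)
    message(sum(miss), " event(s) absent from catalog; imputing f = 1/(N+1) = ",
            format(imput, digits = 4))
    f[miss] <- imput
  }
  names(f) <- keys
  f
}

#' Tumor-pair similarity score
#'
#' Scores whether two tumor samples plausibly arose from a shared lineage,
#' from the cohort frequency f_i of every event in the two samples'
#' combined event universe. Sharing a rare event is strong evidence of
#' shared lineage; the score is the negative natural log of the
#' independence probability of the observed sharing pattern:
#' \deqn{S = -\ln \prod_i \begin{cases}\alpha f_i^2 & i \in a \cap b\\ 1 - f_i^2 & \text{otherwise}\end{cases}}
#' Each shared event contributes \eqn{-\ln(\alpha f_i^2)} (large for rare
#' events); each unshared event contributes \eqn{-\ln(1 - f_i^2)} (small
#' unless the event is near-ubiquitous). With the default \eqn{\alpha = 1}
#' every contribution is nonnegative and the score is a pure independence
#' surprisal. An unshared event with f_i = 1 yields an infinite
#' contribution; the result is returned with `flagged = TRUE` and a
#' warning rather than an error.
#'
#' Events observed in a sample but absent from the catalog (e.g. external
#' pairs) are imputed frequency 1/(N+1) with a message.
#'
#' @param eventsA,eventsB Character vectors of canonical event keys.
#' @param catalog An [EventCatalog].
#' @param alpha Positive co-occurrence scaling; default 1.
#' @param universe `"union"` (default: the two samples' combined events) or
#'   `"catalog"` (all catalog events enter the product; absent-in-both
#'   events count as unshared).
#' @return A [SimilarityResult].
#' @examples
#' cat10 <- new("EventCatalog", cohortSize = 10L,
#'              freq = c("TP53|SNV|p.R273H" = 0.1))
#' similarity(similarityScore("TP53|SNV|p.R273H", "TP53|SNV|p.R273H", cat10))
#' # -log(0.01) = 4.6052
#' @export
similarityScore <- function(eventsA, eventsB, catalog, alpha = 1,
                            universe = c("union", "catalog")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  universe <- match.arg(universe)
  eventsA <- unique(as.character(eventsA))
  eventsB <- unique(as.character(eventsB))
  keys <- if (universe == "union") union(eventsA, eventsB)
          else union(names(eventFreq(catalog)), union(eventsA, eventsB))
  shared <- intersect(eventsA, eventsB)
  if (!length(keys))
    return(new("SimilarityResult", score = 0, sharedEvents = character(0),
               contributions = structure(numeric(0), names = character(0))))
  f <- .catalogLookup(keys, catalog)
  isShared <- keys %in% shared
  contrib <- ifelse(isShared, -log(alpha * f^2), -log(1 - f^2))
  names(contrib) <- keys
  flagged <- any(!isShared & f == 1)
  if (flagged)
    warning("unshared event(s) with cohort frequency 1: ",
            paste(keys[!isShared & f == 1], collapse = ", "),
            "; contribution is +Inf")
  new("SimilarityResult", score = sum(contrib), sharedEvents = shared,
      contributions = contrib, flagged = flagged)
}

#' Permutation null for the similarity score
#'
#' Builds an empirical null distribution of similarity scores from random
#' cross-patient sample pairs: under the null, two biopsies from different
#' patients share only coincidentally recurrent events. Used to convert an
#' observed pre/post pair score into a percentile and a shared-lineage
#' call.
#'
#' @param catalog An [EventCatalog].
#' @param perSampleEvents Named list: sample id -> event keys.
#' @param patientOf Named character vector: sample id -> patient id.
#' @param nPermutations Number of random cross-patient pairs (warning below
#'   100).
#' @param alpha Passed to [similarityScore()].
#' @param seed Integer seed; fixed seed gives identical null quantiles.
#' @return Object of class `"lineageNull"`: list with sorted `scores`,
#'   `alpha`, `nPermutations`, `seed`.
#' @export
calibrateNull <- function(catalog, perSampleEvents, patientOf,
                          nPermutations = 1000L, alpha = 1, seed = 1L) {
  samples <- names(perSampleEvents)
  if (!all(samples %in% names(patientOf)))
    stop("patientOf must cover every sample")
  if (length(unique(patientOf[samples])) < 2L)
    stop("need >= 2 distinct patients to build a cross-patient null")
  if (nPermutations < 100L)
    warning("fewer than 100 permutations; null quantiles will be coarse")
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  scores <- vapply(seq_len(nPermutations), function(i) {
    repeat {
      pick <- sample(samples, 2L)
      if (patientOf[pick[1]] != patientOf[pick[2]]) break
    }
    suppressMessages(similarity(similarityScore(
      perSampleEvents[[pick[1]]], perSampleEvents[[pick[2]]],
      catalog, alpha = alpha)))
  }, numeric(1))
  structure(list(scores = sort(scores), alpha = alpha,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed)),
            class = "lineageNull")
}

#' @export
print.lineageNull <- function(x, ...) {
  qs <- stats::quantile(x$scores, c(0.5, 0.9, 0.95, 0.99))
  cat(sprintf("lineageNull: %d cross-patient pairs (alpha = %g, seed = %d)\n",
              x$nPermutations, x$alpha, x$seed))
  cat("  quantiles:", paste(sprintf("%s=%.3f", names(qs), qs),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Shared-lineage call against a permutation null
#'
#' Annotates a [SimilarityResult] with its percentile within the null and
#' calls shared lineage when the observed score strictly exceeds the
#' configured null percentile (default the 95th). At `percentile = 100` no
#' pair can be called.
#'
#' @param result A [SimilarityResult].
#' @param null A `"lineageNull"` from [calibrateNull()].
#' @param percentile Calling threshold percentile in \[0, 100\].
#' @return The [SimilarityResult] with `nullPercentile` and
#'   `sharedLineageCall` filled in.
#' @export
sharedLineageCall <- function(result, null, percentile = 95) {
  stopifnot(inherits(null, "lineageNull"))
  if (percentile < 0 || percentile > 100)
    stop("percentile must lie in [0, 100]")
  thr <- if (percentile >= 100) Inf
         else stats::quantile(null$scores, percentile / 100, names = FALSE)
  result@nullPercentile <- 100 * mean(null$scores <= result@score)
  result@sharedLineageCall <- result@score > thr
  result
}
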