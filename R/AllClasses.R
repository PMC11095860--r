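#' @import methods
NULL

#' EventCatalog: cohort frequencies of canonical genomic events
#'
#' Holds the cohort size N and, for each canonical event key (see
#' [eventKey()]), its cohort frequency f in (0, 1]. The co-occurrence
#' probability used by the similarity score, p = f^2, is always recomputed
#' from f and never stored.
#'
#' @slot cohortSize Number of samples counted in the denominator.
#' @slot freq Named numeric vector; names are canonical event keys, values
#'   are frequencies in (0, 1]. Events never observed are absent.
#'
#' @seealso [buildCatalog()], [similarityScore()]
#' @export
setClass("EventCatalog",
  representation(cohortSize = "integer", freq = "numeric"),
  prototype(cohortSize = 0L, freq = structure(numeric(0), names = character(0)))
)

setValidity("EventCatalog", function(object) {
  msgs <- character(0)
  if (length(object@cohortSize) != 1L || is.na(object@cohortSize) ||
      object@cohortSize < 1L)
    msgs <- c(msgs, "cohortSize must be a single positive integer")
  f <- object@freq
  if (length(f)) {
    if (is.null(names(f)) || anyDuplicated(names(f)) || any(!nzchar(names(f))))
      msgs <- c(msgs, "freq must have unique non-empty event-key names")
    if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
      msgs <- c(msgs, "all frequencies must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' SampleProfile: one biopsy's molecular profile
#'
#' One sample's filtered variant table, gene-level absolute copy-number
#' calls, tumor mutational burden and purity, tagged with its timepoint
#' relative to therapy.
#'
#' @slot sampleId Sample identifier.
#' @slot timepoint Either `"pre"` or `"post"`.
#' @slot variants data.frame with columns `gene`, `event_class`, `detail`,
#'   `event_key`, `benign`, `chip`, `functional_class`.
#' @slot acnCalls data.frame of gene-level copy-number calls (columns
#'   `gene`, `l`, `purity`, `acn_raw`, `acn`, `category`).
#' @slot tmb Tumor mutational burden in mutations/Mb, or `NA`.
#' @slot purity Tumor purity in (0, 1], or `NA` when unknown.
#' @export
setClass("SampleProfile",
  representation(sampleId = "character", timepoint = "character",
    variants = "data.frame", acnCalls = "data.frame",
    tmb = "numeric", purity = "numeric")
)

setValidity("SampleProfile", function(object) {
  msgs <- character(0)
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msgs <- c(msgs, "sampleId must be a single non-empty string")
  if (!object@timepoint %in% c("pre", "post"))
    msgs <- c(msgs, "timepoint must be 'pre' or 'post'")
  v <- object@variants
  need <- c("gene", "event_class", "detail", "event_key", "benign", "chip",
            "functional_class")
  if (!all(need %in% names(v)))
    msgs <- c(msgs, paste0("variants lacks columns: ",
                           paste(setdiff(need, names(v)), collapse = ", ")))
  else if (nrow(v) && anyDuplicated(v$event_key))
    msgs <- c(msgs, "variant event keys must be unique within a sample")
  p <- object@purity
  if (length(p) == 1L && !is.na(p) && (p <= 0 || p > 1))
    msgs <- c(msgs, "purity must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' PairedCase: one patient's matched pre/post biopsy pair
#'
#' The unit of the whole analysis: a patient's pre- and post-therapy
#' [SampleProfile]s plus therapy category, best response, and the time from
#' therapy start to acquired resistance (AR). By the AR definition used
#' here — progression after objective response or stable disease sustained
#' at least 3 months — `timeToAR` must be >= 3 months.
#'
#' @slot patientId Patient identifier; must match on both profiles.
#' @slot pre,post [SampleProfile] objects for the two timepoints.
#' @slot therapyCategory One of `"ICI-mono"`, `"ICI+CTLA4"`, `"chemo-ICI"`,
#'   `"chemo"`, `"targeted"`, `"mixed"`.
#' @slot bestResponse One of `"CR"`, `"PR"`, `"SD"`.
#' @slot timeToAR Months from therapy start to AR (>= 3).
#' @slot biopsyIntervalMonths Months between the two biopsies, or `NA`.
#' @slot pdl1TpsBin Optional PD-L1 tumor proportion score bin
#'   (`"<1%"`, `"1-49%"`, `">=50%"`) or `NA`.
#' @export
setClass("PairedCase",
  representation(patientId = "character", pre = "SampleProfile",
    post = "SampleProfile", therapyCategory = "character",
    bestResponse = "character", timeToAR = "numeric",
    biopsyIntervalMonths = "numeric", pdl1TpsBin = "character")
)

.THERAPY_CATEGORIES <- c("ICI-mono", "ICI+CTLA4", "chemo-ICI", "chemo",
                         "targeted", "mixed")

setValidity("PairedCase", function(object) {
  msgs <- character(0)
  if (object@pre@timepoint != "pre" || object@post@timepoint != "post")
    msgs <- c(msgs, "pre/post slots must carry matching timepoints")
  if (!object@therapyCategory %in% .THERAPY_CATEGORIES)
    msgs <- c(msgs, paste0("therapyCategory must be one of: ",
                           paste(.THERAPY_CATEGORIES, collapse = ", ")))
  if (!object@bestResponse %in% c("CR", "PR", "SD"))
    msgs <- c(msgs, "bestResponse must be CR, PR or SD")
  if (!is.na(object@timeToAR) && object@timeToAR < 3)
    msgs <- c(msgs, "timeToAR must be >= 3 months (AR definition)")
  if (length(msgs)) msgs else TRUE
})

#' CellFrame: a single-cell spatial table from one tissue sample
#'
#' Cell centroids in microns with marker-positivity flags and an optional
#' cell-class label, together with the tissue area used for densities.
#'
#' @slot cells data.frame with columns `cell_id`, `x`, `y` (microns),
#'   logical marker columns (e.g. `PD1`, `PDL1`, `CD8a`, `CK`) and an
#'   optional `cell_class` column.
#' @slot tissueAreaMm2 Tissue area in mm^2 (> 0).
#' @slot sampleId Sample identifier.
#' @slot timepoint `"pre"`, `"post"` or `NA_character_`.
#' @export
setClass("CellFrame",
  representation(cells = "data.frame", tissueAreaMm2 = "numeric",
    sampleId = "character", timepoint = "character"),
  prototype(tissueAreaMm2 = 1, sampleId = "sample", timepoint = NA_character_)
)

setValidity("CellFrame", function(object) {
  msgs <- character(0)
  cl <- object@cells
  if (!all(c("cell_id", "x", "y") %in% names(cl)))
    msgs <- c(msgs, "cells needs columns cell_id, x, y")
  else {
    if (nrow(cl) && anyDuplicated(cl$cell_id))
      msgs <- c(msgs, "cell_id must be unique within a frame")
    if (nrow(cl) && (any(!is.finite(cl$x)) || any(!is.finite(cl$y))))
      msgs <- c(msgs, "cell coordinates must be finite")
  }
  if (length(object@tissueAreaMm2) != 1L || !is.finite(object@tissueAreaMm2) ||
      object@tissueAreaMm2 <= 0)
    msgs <- c(msgs, "tissueAreaMm2 must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: parameters of the synthetic paired-cohort generator
#'
#' Defines the statistical structure of a simulated matched pre/post cohort:
#' how many patients, the therapy mix, per-event planting probabilities,
#' purity and segment noise, the spatial point-pattern parameters, and the
#' mean paired H-score shift. See [simulateCohort()].
#'
#' @slot nPatients Number of patients (paired cases).
#' @slot therapyMix Named proportions over therapy categories; sums to 1.
#' @slot acquiredEventFreqs Named per-patient planting probabilities for
#'   events acquired in the post sample only (names are canonical event
#'   keys, see [eventKey()]).
#' @slot baselineEventFreqs Named probabilities for events present in both
#'   samples of a pair.
#' @slot biallelicFreq Probability that a planted acquired loss-of-function
#'   mutation is accompanied by a concurrent acquired heterozygous loss of
#'   the same gene (biallelic inactivation).
#' @slot nPrivateEvents Number of patient-private passenger variants planted
#'   in both samples of each pair (the shared-lineage signal).
#' @slot purityRange Interval within (0, 1] from which tumor purity is
#'   drawn uniformly; the same purity is used pre and post.
#' @slot segmentNoiseSd Gaussian noise SD added to segment log2 ratios.
#' @slot spatial List with `areaMm2`, `density` (named cells/mm^2 per cell
#'   class), `targetEngagement` in \[0, 1\].
#' @slot hscoreShift Mean post-minus-pre shift in H-score units.
#' @slot seed Integer seed; identical config + seed reproduces identical
#'   output.
#' @export
setClass("SimConfig",
  representation(nPatients = "integer", therapyMix = "numeric",
    acquiredEventFreqs = "numeric", baselineEventFreqs = "numeric",
    biallelicFreq = "numeric", nPrivateEvents = "integer",
    purityRange = "numeric", segmentNoiseSd = "numeric", spatial = "list",
    hscoreShift = "numeric", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nPatients < 1L)
    msgs <- c(msgs, "nPatients must be positive")
  tm <- object@therapyMix
  if (!length(tm) || is.null(names(tm)))
    msgs <- c(msgs, "therapyMix must be a non-empty named vector")
  else {
    if (!all(names(tm) %in% .THERAPY_CATEGORIES))
      msgs <- c(msgs, "therapyMix names must be known therapy categories")
    if (abs(sum(tm) - 1) > 1e-9)
      msgs <- c(msgs, "therapyMix proportions must sum to 1 (tol 1e-9)")
    if (any(tm < 0)) msgs <- c(msgs, "therapyMix proportions must be >= 0")
  }
  for (nm in c("acquiredEventFreqs", "baselineEventFreqs")) {
    p <- slot(object, nm)
    if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
      msgs <- c(msgs, paste0(nm, " must lie in [0, 1]"))
  }
  if (object@biallelicFreq < 0 || object@biallelicFreq > 1)
    msgs <- c(msgs, "biallelicFreq must lie in [0, 1]")
  pr <- object@purityRange
  if (length(pr) != 2L || any(pr <= 0) || any(pr > 1) || pr[1] > pr[2])
    msgs <- c(msgs, "purityRange must be an interval within (0, 1]")
  if (object@segmentNoiseSd < 0)
    msgs <- c(msgs, "segmentNoiseSd must be >= 0")
  sp <- object@spatial
  if (!all(c("areaMm2", "density", "targetEngagement") %in% names(sp)))
    msgs <- c(msgs, "spatial needs areaMm2, density, targetEngagement")
  else {
    if (sp$areaMm2 <= 0) msgs <- c(msgs, "spatial areaMm2 must be > 0")
    if (any(sp$density < 0)) msgs <- c(msgs, "spatial densities must be >= 0")
    if (sp$targetEngagement < 0 || sp$targetEngagement > 1)
      msgs <- c(msgs, "targetEngagement must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})
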