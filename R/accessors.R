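#' @rdname SampleProfile-class
#' @export
setMethod("sampleId", "SampleProfile", function(x) x@sampleId)
#' @rdname SampleProfile-class
#' @export
setMethod("timepoint", "SampleProfile", function(x) x@timepoint)
#' @rdname SampleProfile-class
#' @export
setMethod("variants", "SampleProfile", function(x) x@variants)
#' @rdname SampleProfile-class
#' @export
setMethod("acnCalls", "SampleProfile", function(x) x@acnCalls)
#' @rdname SampleProfile-class
#' @export
setMethod("purity", "SampleProfile", function(x) x@purity)
#' @rdname SampleProfile-class
#' @export
setMethod("tmb", "SampleProfile", function(x) x@tmb)

#' @rdname CellFrame-class
#' @export
setMethod("sampleId", "CellFrame", function(x) x@sampleId)
#' @rdname CellFrame-class
#' @export
setMethod("timepoint", "CellFrame", function(x) x@timepoint)
#' @rdname CellFrame-class
#' @export
setMethod("cells", "CellFrame", function(x) x@cells)
#' @rdname CellFrame-class
#' @export
setMethod("tissueArea", "CellFrame", function(x) x@tissueAreaMm2)

#' @rdname PairedCase-class
#' @export
setMethod("patientId", "PairedCase", function(x) x@patientId)
#' @rdname PairedCase-class
#' @export
setMethod("preSample", "PairedCase", function(x) x@pre)
#' @rdname PairedCase-class
#' @export
setMethod("postSample", "PairedCase", function(x) x@post)
#' @rdname PairedCase-class
#' @export
setMethod("therapyCategory", "PairedCase", function(x) x@therapyCategory)
#' @rdname PairedCase-class
#' @export
setMethod("bestResponse", "PairedCase", function(x) x@bestResponse)
#' @rdname PairedCase-class
#' @export
setMethod("timeToAR", "PairedCase", function(x) x@timeToAR)

#' @rdname EventCatalog-class
#' @export
setMethod("cohortSize", "EventCatalog", function(x) x@cohortSize)
#' @rdname EventCatalog-class
#' @export
setMethod("eventFreq", "EventCatalog", function(x) x@freq)

#' @rdname EventCatalog-class
#' @export
setMethod("show", "EventCatalog", function(object) {
  cat("EventCatalog with", length(object@freq), "events over",
      object@cohortSize, "samples\n")
  if (length(object@freq)) {
    top <- sort(object@freq, decreasing = TRUE)
    top <- utils::head(top, 5L)
    for (i in seq_along(top))
      cat(sprintf("  %-40s f = %.4g\n", names(top)[i], top[i]))
    if (length(object@freq) > 5L) cat("  ...\n")
  }
  invisible(NULL)
})

#' @rdname SampleProfile-class
#' @export
setMethod("show", "SampleProfile", function(object) {
  cat(sprintf("SampleProfile %s [%s]: %d variants, %d gene ACN calls, purity %s\n",
              object@sampleId, object@timepoint, nrow(object@variants),
              nrow(object@acnCalls),
              ifelse(is.na(object@purity), "NA",
                     format(object@purity, digits = 3))))
  invisible(NULL)
})

#' @rdname PairedCase-class
#' @export
setMethod("show", "PairedCase", function(object) {
  cat(sprintf("PairedCase %s (%s, best response %s, time to AR %s mo)\n",
              object@patientId, object@therapyCategory, object@bestResponse,
              format(object@timeToAR, digits = 3)))
  cat("  pre : "); show(object@pre)
  cat("  post: "); show(object@post)
  invisible(NULL)
})

#' @rdname CellFrame-class
#' @export
setMethod("show", "CellFrame", function(object) {
  mk <- setdiff(names(object@cells), c("cell_id", "x", "y", "cell_class"))
  cat(sprintf("CellFrame %s [%s]: %d cells over %.3g mm^2; markers: %s\n",
              object@sampleId, object@timepoint, nrow(object@cells),
              object@tissueAreaMm2, paste(mk, collapse = ", ")))
  invisible(NULL)
})

#' @rdname SimConfig-class
#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d patients, %d acquired / %d baseline event",
                     " freqs, purity [%.2f, %.2f], seed %d\n"),
              object@nPatients, length(object@acquiredEventFreqs),
              length(object@baselineEventFreqs), object@purityRange[1],
              object@purityRange[2], object@seed))
  invisible(NULL)
})
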