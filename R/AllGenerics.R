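#' @rdname SampleProfile-class
#' @param object,x An object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname SampleProfile-class
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))
#' @rdname SampleProfile-class
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname SampleProfile-class
#' @export
setGeneric("acnCalls", function(x) standardGeneric("acnCalls"))
#' @rdname SampleProfile-class
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))
#' @rdname SampleProfile-class
#' @export
setGeneric("tmb", function(x) standardGeneric("tmb"))

#' @rdname PairedCase-class
#' @param x An object.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname PairedCase-class
#' @export
setGeneric("preSample", function(x) standardGeneric("preSample"))
#' @rdname PairedCase-class
#' @export
setGeneric("postSample", function(x) standardGeneric("postSample"))
#' @rdname PairedCase-class
#' @export
setGeneric("therapyCategory", function(x) standardGeneric("therapyCategory"))
#' @rdname PairedCase-class
#' @export
setGeneric("bestResponse", function(x) standardGeneric("bestResponse"))
#' @rdname PairedCase-class
#' @export
setGeneric("timeToAR", function(x) standardGeneric("timeToAR"))

#' @rdname EventCatalog-class
#' @param x An object.
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))
#' @rdname EventCatalog-class
#' @export
setGeneric("eventFreq", function(x) standardGeneric("eventFreq"))

#' @rdname CellFrame-class
#' @param x An object.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname CellFrame-class
#' @export
setGeneric("tissueArea", function(x) standardGeneric("tissueArea"))
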