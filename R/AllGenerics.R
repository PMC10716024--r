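#' Accessor generics for mpsize classes
#'
#' Small accessor generics used across the package's S4 classes; prefer
#' these over direct slot access.
#'
#' @param object an mpsize S4 object.
#' @name mpsize-accessors
#' @return The corresponding slot value.
NULL

#' @rdname mpsize-accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname mpsize-accessors
#' @export
setGeneric("measurementId", function(object) standardGeneric("measurementId"))

#' @rdname mpsize-accessors
#' @export
setGeneric("dayId", function(object) standardGeneric("dayId"))

#' @rdname mpsize-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname mpsize-accessors
#' @export
setGeneric("peakContrast", function(object) standardGeneric("peakContrast"))

#' @rdname mpsize-accessors
#' @export
setGeneric("peakWidth", function(object) standardGeneric("peakWidth"))

#' @rdname mpsize-accessors
#' @export
setGeneric("eventCount", function(object) standardGeneric("eventCount"))

#' @rdname mpsize-accessors
#' @export
setGeneric("peakLabel", function(object) standardGeneric("peakLabel"))

#' @rdname mpsize-accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname mpsize-accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname mpsize-accessors
#' @export
setGeneric("calibrationFamily", function(object) standardGeneric("calibrationFamily"))

#' @rdname mpsize-accessors
#' @export
setGeneric("calibrationPoints", function(object) standardGeneric("calibrationPoints"))

#' @rdname mpsize-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname mpsize-accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))
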