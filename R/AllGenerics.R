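#' @rdname callCNA
#' @export
setGeneric("callCNA", function(x, gainThreshold = 2.5, lossThreshold = 1.5)
    standardGeneric("callCNA"))

#' @rdname runCnaDE
#' @export
setGeneric("runCnaDE", function(x, calls, minProp = 0.2, minGroupSize = 2L,
                                dropNA = FALSE)
    standardGeneric("runCnaDE"))

#' @rdname CNAExperiment-accessors
#' @export
setGeneric("geValues", function(x) standardGeneric("geValues"))

#' @rdname CNAExperiment-accessors
#' @export
setGeneric("cnValues", function(x) standardGeneric("cnValues"))

#' @rdname CNAExperiment-accessors
#' @export
setGeneric("cnaCalls", function(x) standardGeneric("cnaCalls"))

#' @rdname CNAExperiment-accessors
#' @export
setGeneric("callThresholds", function(x) standardGeneric("callThresholds"))
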