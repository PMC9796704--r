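#' @rdname PatchNetwork-class
#' @param x a \code{PatchNetwork} (or other object with patches).
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname PatchNetwork-class
#' @export
setGeneric("patchIds", function(x) standardGeneric("patchIds"))

#' @rdname PatchNetwork-class
#' @export
setGeneric("patchLengths", function(x) standardGeneric("patchLengths"))

#' @rdname PatchNetwork-class
#' @export
setGeneric("patchCoords", function(x) standardGeneric("patchCoords"))

#' @rdname PatchNetwork-class
#' @export
setGeneric("patchDistances", function(x) standardGeneric("patchDistances"))

#' @rdname DetectionHistory-class
#' @export
setGeneric("nYears", function(x) standardGeneric("nYears"))

#' @rdname DetectionHistory-class
#' @export
setGeneric("yearLabels", function(x) standardGeneric("yearLabels"))

#' @rdname DetectionHistory-class
#' @export
setGeneric("numVisits", function(x) standardGeneric("numVisits"))

#' @rdname DetectionHistory-class
#' @export
setGeneric("detectionArray", function(x) standardGeneric("detectionArray"))

#' @rdname ModelSpec-class
#' @export
setGeneric("modelLabel", function(x) standardGeneric("modelLabel"))

#' @rdname PosteriorSamples-class
#' @export
setGeneric("posteriorDraws", function(x, ...) standardGeneric("posteriorDraws"))

#' @rdname PosteriorSamples-class
#' @export
setGeneric("posteriorSummary", function(x, ...) standardGeneric("posteriorSummary"))

#' @rdname PosteriorSamples-class
#' @export
setGeneric("latentStateDraws", function(x) standardGeneric("latentStateDraws"))

#' @rdname PosteriorSamples-class
#' @export
setGeneric("modelProbabilities", function(x) standardGeneric("modelProbabilities"))

#' @rdname PosteriorSamples-class
#' @export
setGeneric("convergenceDiagnostics", function(x, ...) standardGeneric("convergenceDiagnostics"))
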