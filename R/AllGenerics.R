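#' @import methods
NULL

#' @export
setGeneric("rangeMap", function(x) standardGeneric("rangeMap"))

#' @export
setGeneric("leftImage", function(x) standardGeneric("leftImage"))

#' @export
setGeneric("rightImage", function(x) standardGeneric("rightImage"))

#' @export
setGeneric("sceneGeometry", function(x) standardGeneric("sceneGeometry"))

#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @export
setGeneric("groundtruth", function(x) standardGeneric("groundtruth"))

#' @export
setGeneric("tiltSigned", function(x) standardGeneric("tiltSigned"))

#' @export
setGeneric("tiltUnsigned", function(x) standardGeneric("tiltUnsigned"))

#' @export
setGeneric("slantMap", function(x) standardGeneric("slantMap"))

#' @export
setGeneric("definedMask", function(x, ...) standardGeneric("definedMask"))

#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' @export
setGeneric("disparityMap", function(x) standardGeneric("disparityMap"))

#' @export
setGeneric("halfOcclusionMask", function(x) standardGeneric("halfOcclusionMask"))

#' @export
setGeneric("cueMap", function(x, cue) standardGeneric("cueMap"))

#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setGeneric("poolingTable", function(x) standardGeneric("poolingTable"))

#' @export
setGeneric("fittedDiameter", function(x) standardGeneric("fittedDiameter"))
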