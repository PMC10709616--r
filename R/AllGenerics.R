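#' @rdname GradientSet-class
#' @param object,x a `GradientSet`
#' @export
setGeneric("gradientValues", function(x) standardGeneric("gradientValues"))

#' @rdname GradientSet-class
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @rdname GradientSet-class
#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))

#' @rdname GradientSet-class
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' @rdname GradientSet-class
#' @export
setGeneric("nGradients", function(x) standardGeneric("nGradients"))

#' @rdname ThoughtPCA-class
#' @param x a `ThoughtPCA`
#' @export
setGeneric("componentLoadings", function(x) standardGeneric("componentLoadings"))

#' @rdname ThoughtPCA-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname ParcelGLMFit-class
#' @param x a `ParcelGLMFit`
#' @export
setGeneric("contrastEstimates", function(x) standardGeneric("contrastEstimates"))

#' @rdname ParcelGLMFit-class
#' @export
setGeneric("zMaps", function(x) standardGeneric("zMaps"))
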