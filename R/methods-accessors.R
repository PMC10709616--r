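#' @rdname GradientSet-class
#' @aliases gradientValues,GradientSet-method
#' @export
setMethod("gradientValues", "GradientSet", function(x) x@values)

#' @rdname GradientSet-class
#' @export
setMethod("networkLabels", "GradientSet", function(x) x@networks)

#' @rdname GradientSet-class
#' @export
setMethod("parcelIds", "GradientSet", function(x) rownames(x@values))

#' @rdname GradientSet-class
#' @export
setMethod("nParcels", "GradientSet", function(x) nrow(x@values))

#' @rdname GradientSet-class
#' @export
setMethod("nGradients", "GradientSet", function(x) ncol(x@values))

setMethod("show", "GradientSet", function(object) {
  cat("GradientSet with", nParcels(object), "parcels and",
      nGradients(object), "gradients\n")
  cat("  networks:", paste(levels(object@networks), collapse = ", "), "\n")
  cat("  provenance:", object@provenance, "\n")
})

#' @rdname ThoughtPCA-class
#' @export
setMethod("componentLoadings", "ThoughtPCA", function(x) x@loadings)

#' @rdname ThoughtPCA-class
#' @export
setMethod("varianceExplained", "ThoughtPCA", function(x) x@varianceExplained)

setMethod("show", "ThoughtPCA", function(object) {
  k <- ncol(object@loadings)
  cat("ThoughtPCA:", nrow(object@loadings), "items,", k,
      "varimax-rotated components, fitted to", object@nObs, "observations\n")
  cat(sprintf("  variance explained: %s (total %.2f%%)\n",
              paste(sprintf("%.2f%%", object@varianceExplained), collapse = ", "),
              sum(object@varianceExplained)))
})

#' @rdname ParcelGLMFit-class
#' @export
setMethod("contrastEstimates", "ParcelGLMFit", function(x) x@beta)

#' @rdname ParcelGLMFit-class
#' @export
setMethod("zMaps", "ParcelGLMFit", function(x) x@z)

setMethod("show", "ParcelGLMFit", function(object) {
  cat("ParcelGLMFit (", object@level, " level): ", nrow(object@beta),
      " parcels x ", ncol(object@beta), " contrasts, dof = ",
      object@dof, "\n", sep = "")
})
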