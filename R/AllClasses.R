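#' @import methods
NULL

#' GradientSet: a parcellated gradient coordinate system
#'
#' Holds k macroscale connectivity gradient maps over P parcels, together
#' with parcel identifiers and a 7-network label per parcel. The gradient
#' values define the axes of the neural state space: any brain map located
#' in the space receives one Spearman correlation coordinate per gradient.
#'
#' @slot values numeric matrix, parcels x gradients; rownames are parcel
#'   ids, colnames gradient names.
#' @slot networks factor of length \code{nrow(values)} with one of the
#'   seven canonical cortical network labels per parcel.
#' @slot provenance character scalar describing where the maps came from
#'   (e.g. a repository accession, or the seed of a synthetic construction).
#'
#' @seealso [makeGradients()], [computeCoordinates()], [networkSummary()]
#' @export
setClass("GradientSet",
  representation(
    values = "matrix",
    networks = "factor",
    provenance = "character"
  )
)

setValidity("GradientSet", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (ncol(v) < 1L) msg <- c(msg, "at least one gradient is required")
  if (anyNA(v) || any(!is.finite(v))) {
    msg <- c(msg, "gradient values must be finite and non-missing")
  }
  if (is.null(rownames(v))) msg <- c(msg, "'values' must carry parcel ids as rownames")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate parcel ids")
  if (length(object@networks) != nrow(v)) {
    msg <- c(msg, "one network label per parcel is required")
  }
  if (anyNA(object@networks)) msg <- c(msg, "network labels must not be missing")
  if (length(msg)) msg else TRUE
})

#' Construct a GradientSet from a value matrix and network labels
#'
#' @param values parcels x gradients numeric matrix; rownames are parcel
#'   ids (generated as `p0001, ...` when absent).
#' @param networks character or factor of network labels, one per parcel.
#' @param provenance free-text description of the maps' origin.
#' @return a [GradientSet-class].
#' @export
GradientSet <- function(values, networks, provenance = "user-supplied") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("gradient_", seq_len(ncol(values)))
  }
  if (!is.factor(networks)) {
    networks <- factor(networks, levels = unique(networks))
  }
  new("GradientSet", values = values, networks = networks,
      provenance = provenance)
}

#' ThoughtPCA: a varimax-rotated probe-level PCA model
#'
#' The result of fitting a correlation-matrix PCA with varimax rotation to
#' an observations x items matrix of experience sampling ratings. Stores
#' the training item means and standard deviations so that new data --
#' including an external dataset -- can be scored on exactly the training
#' scale, by the dot product of standardized items with the rotated
#' loadings.
#'
#' @slot itemMeans,itemSds named numeric vectors, one entry per item.
#' @slot loadings numeric matrix, items x components, varimax-rotated,
#'   ordered by descending rotated variance, sign-anchored so the
#'   largest-magnitude item loads positively on each component.
#' @slot varianceExplained numeric vector, percentage of total item
#'   variance per rotated component.
#' @slot nObs number of probe observations the model was fitted to.
#'
#' @seealso [fitThoughtPCA()], [scoreProbes()], [projectExternal()]
#' @export
setClass("ThoughtPCA",
  representation(
    itemMeans = "numeric",
    itemSds = "numeric",
    loadings = "matrix",
    varianceExplained = "numeric",
    nObs = "integer"
  )
)

setValidity("ThoughtPCA", function(object) {
  msg <- character()
  p <- length(object@itemMeans)
  if (length(object@itemSds) != p) msg <- c(msg, "itemMeans/itemSds length mismatch")
  if (any(object@itemSds <= 0)) msg <- c(msg, "item standard deviations must be positive")
  if (nrow(object@loadings) != p) msg <- c(msg, "loadings must have one row per item")
  k <- ncol(object@loadings)
  if (length(object@varianceExplained) != k) {
    msg <- c(msg, "one variance-explained entry per component is required")
  }
  tot <- sum(object@varianceExplained)
  if (!is.finite(tot) || tot <= 0 || tot > 100 + 1e-8) {
    msg <- c(msg, "total variance explained must lie in (0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' ParcelGLMFit: parcel-wise GLM contrast estimates
#'
#' Per-parcel, per-contrast estimates from a first-level GLM (one run) or
#' from precision-weighted fixed-effects averaging of several runs
#' (subject level). z statistics are obtained from t by exact two-sided
#' tail-probability matching.
#'
#' @slot beta,variance,z numeric matrices, parcels x contrasts.
#' @slot dof residual degrees of freedom (Inf at the subject level, where
#'   the combined estimate is treated as normal).
#' @slot level "run" or "subject".
#'
#' @seealso [fitParcelGLM()], [fixedEffectsAverage()]
#' @export
setClass("ParcelGLMFit",
  representation(
    beta = "matrix",
    variance = "matrix",
    z = "matrix",
    dof = "numeric",
    level = "character"
  )
)

setValidity("ParcelGLMFit", function(object) {
  msg <- character()
  d <- dim(object@beta)
  if (!identical(dim(object@variance), d) || !identical(dim(object@z), d)) {
    msg <- c(msg, "beta, variance and z must share dimensions")
  }
  if (any(object@variance < 0, na.rm = TRUE)) msg <- c(msg, "negative variance")
  if (!object@level %in% c("run", "subject")) msg <- c(msg, "level must be 'run' or 'subject'")
  if (length(msg)) msg else TRUE
})
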