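#' Locate a brain map in the gradient state space
#'
#' The coordinate of a map along a gradient is the Spearman rank
#' correlation between the map's parcel values and that gradient's parcel
#' values, computed over the parcels present in both inputs, aligned by
#' parcel id (never by position). Ties receive average ranks. Because the
#' coordinates depend only on ranks, they are invariant under any
#' strictly increasing transform of the map.
#'
#' @param map named numeric vector of parcel values; names are parcel ids.
#' @param gradients a [GradientSet-class].
#' @return named numeric vector of Spearman correlations in `[-1, 1]`,
#'   one per gradient.
#' @examples
#' g <- makeGradients(100, 2, seed = 1)
#' m <- gradientValues(g)[, 1]
#' computeCoordinates(m, g)  # coordinate 1 is exactly 1
#' @export
computeCoordinates <- function(map, gradients) {
  stopifnot(is(gradients, "GradientSet"))
  if (is.null(names(map))) stop("'map' must carry parcel ids as names")
  map <- map[!is.na(map)]
  shared <- intersect(names(map), parcelIds(gradients))
  if (length(shared) < 3L) {
    stop("insufficient overlap: only ", length(shared),
         " shared parcels (need at least 3)")
  }
  dropped <- nParcels(gradients) - length(shared)
  if (dropped > 0L) {
    message(dropped, " gradient parcels absent from the map were dropped")
  }
  x <- map[shared]
  if (stats::sd(x) == 0) stop("constant map: Spearman correlation undefined")
  G <- gradientValues(gradients)[shared, , drop = FALSE]
  rho <- drop(stats::cor(x, G, method = "spearman"))
  stats::setNames(as.numeric(rho), colnames(G))
}

#' Coordinates for a cohort of simulated or fitted maps
#'
#' Applies [computeCoordinates()] to every subject x condition map and
#' returns the tidy long table used by the inference layer.
#'
#' @param maps named list (condition -> subjects x parcels matrix), as
#'   returned by [simulateBrainMaps()], or a single such matrix.
#' @param gradients a [GradientSet-class].
#' @return data.frame with columns subject, condition, dimension, rho.
#' @export
mapCoordinates <- function(maps, gradients) {
  if (is.matrix(maps)) maps <- list(map = maps)
  rows <- lapply(names(maps), function(cond) {
    m <- maps[[cond]]
    do.call(rbind, lapply(rownames(m), function(s) {
      rho <- computeCoordinates(m[s, ], gradients)
      data.frame(subject = s, condition = cond,
                 dimension = seq_along(rho), rho = as.numeric(rho),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-average position of a condition in the state space
#'
#' @param coords tidy coordinate table from [mapCoordinates()].
#' @param condition condition label to summarise.
#' @return data.frame with per-dimension mean, standard error and 95%
#'   confidence limits (t-based; NA with one subject).
#' @export
groupAverageLocation <- function(coords, condition) {
  sub <- coords[coords$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown condition: ", condition)
  out <- do.call(rbind, lapply(split(sub, sub$dimension), function(d) {
    n <- nrow(d)
    m <- mean(d$rho)
    se <- if (n > 1) stats::sd(d$rho) / sqrt(n) else NA_real_
    half <- if (n > 1) stats::qt(0.975, n - 1) * se else NA_real_
    data.frame(condition = condition, dimension = d$dimension[1],
               mean = m, se = se, lower = m - half, upper = m + half,
               n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Network-averaged radar summary of a map or gradient
#'
#' Averages parcel values within each of the seven networks; optionally
#' z-scores the seven network means (as done when comparing profiles
#' across gradients on a common scale). A network with no parcels is
#' reported as NA, not zero.
#'
#' @param values named numeric vector over parcels (a brain map, or one
#'   gradient column).
#' @param gradients a [GradientSet-class] supplying the network labels.
#' @param standardize z-score the seven network means.
#' @return data.frame with columns network, mean (and z when
#'   standardized).
#' @export
networkSummary <- function(values, gradients, standardize = FALSE) {
  stopifnot(is(gradients, "GradientSet"))
  ids <- parcelIds(gradients)
  if (is.null(names(values))) stop("'values' must carry parcel ids as names")
  v <- values[ids]
  nets <- networkLabels(gradients)
  means <- vapply(levels(nets), function(lv) {
    sel <- nets == lv
    if (!any(sel)) NA_real_ else mean(v[sel], na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(network = levels(nets), mean = means,
                    stringsAsFactors = FALSE)
  if (standardize) {
    s <- stats::sd(means, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("network means are constant: standardized summary undefined")
    }
    out$z <- (means - mean(means, na.rm = TRUE)) / s
  }
  out
}
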