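#' Gamma hemodynamic response kernel
#'
#' The canonical single-gamma HRF with mean lag 6 s and standard deviation
#' 3 s (gamma shape 4, scale 1.5), sampled at the repetition time over at
#' least `span` seconds and normalised to unit sum, so that convolving a
#' constant series leaves it unchanged after burn-in.
#'
#' @param tr repetition time in seconds.
#' @param meanLag,sdLag mean and standard deviation of the gamma density
#'   in seconds.
#' @param span minimum kernel support in seconds.
#' @return numeric kernel sampled at `0, tr, 2*tr, ...`, summing to 1.
#' @export
gammaHRF <- function(tr, meanLag = 6, sdLag = 3, span = 32) {
  stopifnot(tr > 0)
  shape <- (meanLag / sdLag)^2
  scale <- sdLag^2 / meanLag
  t <- seq(0, max(span, tr), by = tr)
  k <- stats::dgamma(t, shape = shape, scale = scale)
  k / sum(k)
}

#' Build a first-level design matrix with parametric thought regressors
#'
#' Constructs the six-regressor task design: boxcars for vigilance
#' (non-target) and target periods, a unit boxcar covering the
#' `probeWindow` seconds preceding each probe onset, and -- when probe
#' scores are supplied -- one parametric regressor per thought component,
#' equal to the probe-window boxcar scaled by that probe's component
#' score, mean-centred across the run's probes before convolution.
#' Centring makes the parametric regressors orthogonal to the plain
#' window regressor (the per-probe boxcars are disjoint and of equal
#' mass) and gives them zero mean within the run. All task regressors are
#' convolved with [gammaHRF()]; confound columns are appended
#' unconvolved. An intercept column is always included.
#'
#' Events are sampled onto the volume grid by overlap fraction: a volume
#' spanning `[(v-1)*tr, v*tr)` receives the fraction of the event falling
#' inside it, so a 6-s window at TR 3 s occupies exactly two volumes.
#'
#' @param events event table with columns onset, duration, event_type
#'   (`non_target`, `target`, `probe`); onsets must be strictly
#'   increasing.
#' @param scores probes x components matrix of thought scores, one row
#'   per probe event in onset order, or NULL for a task-only design.
#' @param tr repetition time in seconds.
#' @param nVolumes number of volumes.
#' @param probeWindow reporting window in seconds before each probe.
#' @param confounds optional volumes x q matrix appended unconvolved and
#'   excluded from contrasts.
#'
#' @return an object of class `DesignMatrix`: a list with the numeric
#'   matrix (`matrix`), the task column names eligible for contrasts
#'   (`taskColumns`), `tr` and `nVolumes`.
#' @export
buildDesign <- function(events, scores = NULL, tr, nVolumes,
                        probeWindow = 6, confounds = NULL) {
  if (is.unsorted(events$onset, strictly = TRUE)) {
    stop("event onsets must be strictly increasing")
  }
  if (max(events$onset + events$duration) > nVolumes * tr + 1e-9) {
    stop("events extend beyond the run length")
  }
  boxcar <- function(onset, duration) {
    v <- seq_len(nVolumes)
    lo <- (v - 1) * tr
    pmax(0, pmin(lo + tr, onset + duration) - pmax(lo, onset)) / tr
  }
  sumBoxcar <- function(rows) {
    if (nrow(rows) == 0L) return(numeric(nVolumes))
    Reduce(`+`, Map(boxcar, rows$onset, rows$duration))
  }
  ev1 <- sumBoxcar(events[events$event_type == "non_target", ])
  ev2 <- sumBoxcar(events[events$event_type == "target", ])
  probes <- events[events$event_type == "probe", , drop = FALSE]
  # windows are snapped to whole volumes (2 at TR 3 s) so every probe's
  # boxcar has identical mass and the centred parametric regressors are
  # exactly orthogonal to the plain window regressor
  nWin <- max(1L, round(probeWindow / tr))
  windows <- lapply(probes$onset, function(on) {
    vLast <- floor(on / tr + 1e-9)
    vFirst <- vLast - nWin + 1L
    if (vFirst < 1L) {
      warning("probe window truncated at the start of the run")
      vFirst <- 1L
    }
    w <- numeric(nVolumes)
    w[vFirst:vLast] <- 1
    w
  })
  ev3 <- if (length(windows)) Reduce(`+`, windows) else numeric(nVolumes)
  X <- cbind(vigilance = ev1, target = ev2, probe_window = ev3)
  # all-zero regressors (no events of that type) are dropped
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != nrow(probes)) {
      stop("one score row per probe is required (",
           nrow(probes), " probes, ", nrow(scores), " score rows)")
    }
    centred <- scale(scores, center = TRUE, scale = FALSE)
    for (c in seq_len(ncol(centred))) {
      evc <- numeric(nVolumes)
      for (p in seq_along(windows)) evc <- evc + centred[p, c] * windows[[p]]
      X <- cbind(X, evc)
      colnames(X)[ncol(X)] <- paste0("thought_", c)
    }
  }
  attrRaw <- X
  k <- gammaHRF(tr)
  X <- apply(X, 2, function(col) {
    stats::convolve(col, rev(k), type = "open")[seq_len(nVolumes)]
  })
  taskCols <- colnames(X)
  X <- cbind(intercept = 1, X)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nVolumes) stop("confound rows must match nVolumes")
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
    }
    X <- cbind(X, confounds)
  }
  structure(list(matrix = X, taskColumns = taskCols, tr = tr,
                 nVolumes = nVolumes, raw = attrRaw),
            class = "DesignMatrix")
}

#' @rdname buildDesign
#' @param design a `DesignMatrix`.
#' @export
designMatrix <- function(design) design$matrix

#' @export
print.DesignMatrix <- function(x, ...) {
  cat("DesignMatrix:", x$nVolumes, "volumes x", ncol(x$matrix),
      "columns (TR", x$tr, "s)\n")
  cat("  task columns:", paste(x$taskColumns, collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian-weighted running-line highpass filter
#'
#' Removes slow drift by subtracting, at each timepoint, the value of a
#' locally weighted straight-line fit whose weights are a Gaussian of
#' standard deviation `sigma` seconds centred on that timepoint. Any
#' globally linear trend is removed exactly; series length is preserved.
#'
#' @param x numeric vector or volumes x parcels matrix.
#' @param sigma Gaussian weight standard deviation in seconds.
#' @param tr repetition time in seconds; must be smaller than `sigma`.
#' @return filtered series of the same shape.
#' @export
highpassFilter <- function(x, sigma = 50, tr = 3) {
  if (sigma <= tr) stop("'sigma' must exceed the repetition time")
  wasVector <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("series too short to filter (need at least 3 volumes)")
  times <- (seq_len(n) - 1) * tr
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- stats::dnorm(times, mean = times[i], sd = sigma)
    Xl <- cbind(1, times - times[i])
    WX <- Xl * w
    S[i, ] <- (solve(crossprod(Xl, WX), t(WX)))[1, ]
  }
  out <- x - S %*% x
  if (wasVector) out <- drop(out)
  out
}
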