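#' Expand named contrast weights over a design
#'
#' @param design a `DesignMatrix`.
#' @param contrasts named list; each element a named numeric vector whose
#'   names are task columns of the design (e.g.
#'   `list(vigilance = c(vigilance = 1))`). Weights on confound or
#'   intercept columns are rejected.
#' @return contrasts x columns weight matrix over the full design.
#' @export
expandContrasts <- function(design, contrasts) {
  cols <- colnames(designMatrix(design))
  C <- matrix(0, length(contrasts), length(cols),
              dimnames = list(names(contrasts), cols))
  for (i in seq_along(contrasts)) {
    w <- contrasts[[i]]
    bad <- setdiff(names(w), design$taskColumns)
    if (length(bad)) {
      stop("contrast '", names(contrasts)[i],
           "' weights non-task columns: ", paste(bad, collapse = ", "))
    }
    C[i, names(w)] <- w
  }
  C
}

#' Fit the first-level GLM to every parcel of one run
#'
#' Ordinary least squares per parcel with a shared design; for each
#' contrast, `t = c'b / se(c'b)` and a z statistic obtained from t by
#' exact two-sided tail-probability matching (not a large-dof
#' approximation). An all-zero contrast yields beta 0 and an NA z rather
#' than NaN propagation.
#'
#' @param timeseries volumes x parcels numeric matrix.
#' @param design a [buildDesign()] result.
#' @param contrasts named list of named weight vectors (see
#'   [expandContrasts()]); defaults to one unit contrast per task column.
#' @return a [ParcelGLMFit-class] at the run level.
#' @export
fitParcelGLM <- function(timeseries, design, contrasts = NULL) {
  X <- designMatrix(design)
  Y <- as.matrix(timeseries)
  if (nrow(Y) != nrow(X)) {
    stop("time series has ", nrow(Y), " volumes but the design has ", nrow(X))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  if (is.null(contrasts)) {
    contrasts <- stats::setNames(
      lapply(design$taskColumns, function(cn) stats::setNames(1, cn)),
      design$taskColumns)
  }
  C <- expandContrasts(design, contrasts)
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dof
  XtXinv <- solve(crossprod(X))
  cvar <- rowSums((C %*% XtXinv) * C)  # c' (X'X)^-1 c per contrast
  cb <- t(C %*% B)                      # parcels x contrasts
  v <- outer(sigma2, cvar)              # parcels x contrasts
  tstat <- cb / sqrt(v)
  z <- zFromT(tstat, dof)
  z[, cvar == 0] <- NA_real_
  dimnames(cb) <- list(colnames(Y), rownames(C))
  dimnames(v) <- dimnames(cb); dimnames(z) <- dimnames(cb)
  new("ParcelGLMFit", beta = cb, variance = v, z = z,
      dof = dof, level = "run")
}

# z with the same two-sided tail probability as t at the given dof,
# computed on the log scale to stay finite for extreme statistics
zFromT <- function(tstat, dof) {
  logp <- stats::pt(abs(tstat), df = dof, lower.tail = FALSE, log.p = TRUE)
  sign(tstat) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
}

#' Precision-weighted fixed-effects averaging across runs
#'
#' Combines run-level contrast estimates within a subject by inverse
#' variance weighting: `b = sum(b_r / v_r) / sum(1 / v_r)`,
#' `v = 1 / sum(1 / v_r)`; z is recomputed from the combined estimate
#' under normality. A single run passes through unchanged (relabelled to
#' the subject level).
#'
#' @param runFits list of run-level [ParcelGLMFit-class] objects sharing
#'   parcels and contrasts.
#' @return a subject-level [ParcelGLMFit-class].
#' @export
fixedEffectsAverage <- function(runFits) {
  stopifnot(length(runFits) >= 1)
  ref <- dimnames(runFits[[1]]@beta)
  for (f in runFits) {
    if (!identical(dimnames(f@beta), ref)) {
      stop("runs disagree on parcels or contrasts; cannot average")
    }
  }
  W <- lapply(runFits, function(f) 1 / f@variance)
  sumW <- Reduce(`+`, W)
  num <- Reduce(`+`, Map(function(f, w) f@beta * w, runFits, W))
  beta <- num / sumW
  v <- 1 / sumW
  z <- beta / sqrt(v)
  z[!is.finite(v)] <- NA_real_
  new("ParcelGLMFit", beta = beta, variance = v, z = z,
      dof = Inf, level = "subject")
}
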