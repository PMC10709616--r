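#' Probe-level PCA of experience sampling ratings with varimax rotation
#'
#' Fits a correlation-matrix PCA (items z-scored by their column mean and
#' standard deviation) to the observations x 13 probe matrix, retains the
#' top `k` components and rotates them with varimax (Kaiser
#' row-normalisation, tolerance 1e-6). Components are re-ordered by
#' descending rotated variance and sign-anchored so that each component's
#' largest-magnitude item loads positively, making the solution
#' reproducible. Variance explained is reported after rotation; rotation
#' preserves per-item communalities and the total retained variance.
#'
#' @param probes a probe matrix data.frame containing the 13 item columns
#'   (`item_1` ... `item_13`); rows with missing item values are dropped
#'   with a message.
#' @param k number of components to retain (1 to 13). The analyses this
#'   package reproduces retain three; [kaiserK()] offers an
#'   eigenvalue-greater-than-one helper.
#' @return a [ThoughtPCA-class].
#' @export
fitThoughtPCA <- function(probes, k = 3L) {
  items <- mdesItemNames()
  missing <- setdiff(items, colnames(probes))
  if (length(missing)) {
    stop("probe matrix lacks item columns: ", paste(missing, collapse = ", "))
  }
  if (k < 1 || k > length(items)) stop("'k' must lie between 1 and 13")
  X <- as.matrix(probes[, items])
  complete <- stats::complete.cases(X)
  if (!all(complete)) {
    message(sum(!complete), " probe rows with missing items dropped")
    X <- X[complete, , drop = FALSE]
  }
  if (nrow(X) < length(items)) stop("need at least 13 complete probe rows")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance item(s): ", paste(items[sdv == 0], collapse = ", "))
  }
  Z <- scale(X, center = mu, scale = sdv)
  ei <- eigen(stats::cor(X), symmetric = TRUE)
  A <- ei$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ei$values[seq_len(k)], 0)), k)
  L <- if (k > 1) {
    rot <- stats::varimax(A, normalize = TRUE, eps = 1e-6)
    A %*% rot$rotmat
  } else A
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(items, paste0("component_", seq_len(k)))
  new("ThoughtPCA",
      itemMeans = stats::setNames(mu, items),
      itemSds = stats::setNames(sdv, items),
      loadings = L,
      varianceExplained = 100 * colSums(L^2) / length(items),
      nObs = nrow(X))
}

#' Eigenvalue-greater-than-one component count
#' @param probes a probe matrix with the 13 item columns.
#' @return integer, the number of correlation-matrix eigenvalues above 1.
#' @export
kaiserK <- function(probes) {
  X <- as.matrix(probes[, mdesItemNames()])
  sum(eigen(stats::cor(X[stats::complete.cases(X), ]),
            symmetric = TRUE, only.values = TRUE)$values > 1)
}

#' Score probes on a fitted thought-pattern model
#'
#' Per-probe component scores are the dot product of the standardized
#' item ratings with the rotated loadings, standardizing by the model's
#' training means and standard deviations. Applied to the training data
#' this reproduces the fit-time scores exactly.
#'
#' @param model a [ThoughtPCA-class].
#' @param probes a probe matrix containing the model's item columns.
#' @return data.frame with the key columns present in `probes`
#'   (participant, session, run, probe_index) and one `score_c` column
#'   per component.
#' @export
scoreProbes <- function(model, probes) {
  items <- names(model@itemMeans)
  missing <- setdiff(items, colnames(probes))
  if (length(missing)) {
    stop("item alignment failure; absent from the data: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(probes[, items])
  Z <- scale(X, center = model@itemMeans, scale = model@itemSds)
  S <- Z %*% model@loadings
  colnames(S) <- sub("^component", "score", colnames(model@loadings))
  keys <- intersect(c("participant", "session", "run", "probe_index",
                      "context", "probe_order", "day", "order"),
                    colnames(probes))
  out <- cbind(probes[, keys, drop = FALSE], as.data.frame(S))
  rownames(out) <- NULL
  out
}

#' Project an external experience sampling dataset onto fitted components
#'
#' Identical arithmetic to [scoreProbes()], exposed separately to make
#' the cross-dataset contract explicit: the external ratings are scaled
#' by the *training* dataset's item means and standard deviations (never
#' the external set's own), then dotted with the training loadings. One
#' score row per external observation is returned.
#'
#' @param model a [ThoughtPCA-class] fitted to the reference dataset.
#' @param external a probe matrix from another study using the same 13
#'   items.
#' @return data.frame of projected scores, one row per observation.
#' @export
projectExternal <- function(model, external) {
  scoreProbes(model, external)
}

#' Per-participant mean component scores
#'
#' @param scores a [scoreProbes()] result.
#' @return data.frame, one row per participant, mean of each score column
#'   over all of that participant's probes (across runs).
#' @export
participantMeans <- function(scores) {
  sc <- grep("^score_", colnames(scores), value = TRUE)
  if (nrow(scores) == 0L) {
    return(scores[, c("participant", sc), drop = FALSE])
  }
  agg <- stats::aggregate(scores[, sc, drop = FALSE],
                          by = list(participant = scores$participant), mean)
  agg[order(agg$participant), , drop = FALSE]
}

#' Run-wise consistency ICC of component scores
#'
#' Intraclass correlation of per-run participant mean scores across runs:
#' two-way mixed-effects model, consistency type, single measure
#' (ICC(3,1)), computed from the ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k - 1) MSE)`. Participants lacking any run are
#' excluded with a message.
#'
#' @param scores a [scoreProbes()] result with `participant` and `run`
#'   columns.
#' @param component component index.
#' @return the ICC, a value in `(-1, 1]`.
#' @export
iccConsistency <- function(scores, component = 1L) {
  col <- paste0("score_", component)
  if (!col %in% colnames(scores)) stop("no such component: ", component)
  perRun <- stats::aggregate(scores[[col]],
                             by = list(participant = scores$participant,
                                       run = scores$run), mean)
  wide <- stats::reshape(perRun, idvar = "participant", timevar = "run",
                         direction = "wide")
  M <- as.matrix(wide[, -1, drop = FALSE])
  complete <- stats::complete.cases(M)
  if (!all(complete)) {
    message(sum(!complete), " participants with missing runs excluded")
    M <- M[complete, , drop = FALSE]
  }
  n <- nrow(M); k <- ncol(M)
  if (k < 2L) stop("at least two runs are required")
  if (n < 2L) stop("ICC undefined with fewer than two participants")
  grand <- mean(M)
  msr <- k * sum((rowMeans(M) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(M) - grand)^2) / (k - 1)
  sst <- sum((M - grand)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence coefficients
#' `phi(a, b) = |a . b| / (||a|| ||b||)`, with columns of `B` greedily
#' matched to columns of `A` (sign- and order-invariant), as used to
#' compare factor solutions.
#'
#' @param A,B loading matrices with equal row counts.
#' @return numeric vector, one matched congruence per column of `A`.
#' @export
tuckerCongruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  phi <- abs(crossprod(A, B)) /
    outer(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  out <- numeric(ncol(A))
  avail <- seq_len(ncol(B))
  for (j in seq_len(ncol(A))) {
    best <- avail[which.max(phi[j, avail])]
    out[j] <- phi[j, best]
    avail <- setdiff(avail, best)
    if (!length(avail)) avail <- seq_len(ncol(B))
  }
  out
}
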