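#' Simulate subject-level brain maps as planted gradient mixtures
#'
#' Builds one parcel map per subject and condition as a linear mixture of
#' the standardized gradient maps plus independent Gaussian parcel noise:
#' `map = sum_i w_i * z(gradient_i) + noise`. At zero noise the recovered
#' Spearman coordinates are monotone in the planted mixing weights, which
#' is what makes these maps a usable ground truth for the state-space
#' layer.
#'
#' @param gradients a [GradientSet-class].
#' @param truth a [plantedTruth()] object; `truth$coordinates` must supply
#'   a weight vector of length `nGradients(gradients)` per condition.
#' @param nSubjects number of subjects.
#' @param noiseSd standard deviation of parcel noise.
#' @param seed integer seed.
#' @param conditions which planted conditions to simulate (default all).
#'
#' @return named list, one element per condition, each a subjects x
#'   parcels numeric matrix with subject ids as rownames and parcel ids as
#'   colnames.
#' @export
simulateBrainMaps <- function(gradients, truth, nSubjects, noiseSd = 0.5,
                              seed = 1L,
                              conditions = names(truth$coordinates)) {
  stopifnot(is(gradients, "GradientSet"))
  k <- nGradients(gradients)
  P <- nParcels(gradients)
  w <- truth$coordinates[conditions]
  if (any(vapply(w, is.null, logical(1)))) {
    stop("planted coordinates missing for: ",
         paste(conditions[vapply(w, is.null, logical(1))], collapse = ", "))
  }
  bad <- vapply(w, length, integer(1)) != k
  if (any(bad)) {
    stop("weight length does not match the number of gradients for: ",
         paste(conditions[bad], collapse = ", "))
  }
  Z <- scale(gradientValues(gradients))
  set.seed(seed)
  subjects <- sprintf("sub%03d", seq_len(nSubjects))
  out <- lapply(w, function(wi) {
    base <- as.numeric(Z %*% wi)
    m <- matrix(rep(base, each = nSubjects), nrow = nSubjects,
                dimnames = list(subjects, parcelIds(gradients)))
    m + matrix(stats::rnorm(nSubjects * P, sd = noiseSd), nrow = nSubjects)
  })
  names(out) <- conditions
  out
}
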