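#' Simulation configuration for a synthetic cohort
#'
#' Bundles the acquisition and task parameters of the study design the
#' simulators emulate: a sustained-attention task acquired at TR 3 s with
#' 267 volumes per run, three runs per participant, trials of 3 s with
#' 1.5--2.5 s jittered inter-stimulus intervals, 20% infrequent targets,
#' and eight experience sampling probes per run placed in vigilance
#' periods.
#'
#' @param nParticipants number of participants.
#' @param nRuns runs per participant.
#' @param probesPerRun experience sampling probes per run.
#' @param nParcels parcels in simulated maps and time series.
#' @param tr repetition time in seconds.
#' @param nVolumes volumes per run.
#' @param targetFraction proportion of experimental trials that are
#'   targets; must lie strictly between 0 and 1.
#' @param isiRange length-2 numeric, jittered inter-stimulus interval in
#'   seconds.
#' @param trialDuration duration of one experimental trial in seconds.
#' @param probeWindow seconds before each probe treated as its reporting
#'   window; snapped to whole volumes downstream.
#' @param probeDuration seconds one full 13-item probe occupies on screen.
#' @param noiseSd default noise standard deviation used by the simulators.
#' @param nMissingRun number of participants who lose one run (seeded
#'   choice of which).
#' @param seed integer seed recorded in the configuration.
#'
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nParticipants = 62L, nRuns = 3L,
                             probesPerRun = 8L, nParcels = 400L,
                             tr = 3, nVolumes = 267L,
                             targetFraction = 0.20,
                             isiRange = c(1.5, 2.5),
                             trialDuration = 3,
                             probeWindow = 6,
                             probeDuration = 58.5,
                             noiseSd = 0.5,
                             nMissingRun = 0L,
                             seed = 1L) {
  counts <- c(nParticipants = nParticipants, nRuns = nRuns,
              probesPerRun = probesPerRun, nParcels = nParcels,
              nVolumes = nVolumes)
  if (any(counts < 1)) {
    stop("all counts must be >= 1; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  if (targetFraction <= 0 || targetFraction >= 1) {
    stop("'targetFraction' must lie strictly between 0 and 1")
  }
  if (length(isiRange) != 2L || isiRange[1] > isiRange[2] || any(isiRange < 0)) {
    stop("'isiRange' must be an increasing non-negative pair of seconds")
  }
  if (probeWindow <= 0) stop("'probeWindow' must be positive")
  if (nMissingRun > nParticipants) stop("more missing runs than participants")
  structure(
    list(nParticipants = as.integer(nParticipants), nRuns = as.integer(nRuns),
         probesPerRun = as.integer(probesPerRun), nParcels = as.integer(nParcels),
         tr = tr, nVolumes = as.integer(nVolumes),
         targetFraction = targetFraction, isiRange = isiRange,
         trialDuration = trialDuration, probeWindow = probeWindow,
         probeDuration = probeDuration, noiseSd = noiseSd,
         nMissingRun = as.integer(nMissingRun), seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Default 13 x 3 planted item loading matrix
#'
#' A simple-structure loading matrix for three latent thought components
#' over 13 rating items: items 1--5 carry the first component, 6--9 the
#' second, 10--13 the third, with mild cross-loadings so recovery is not
#' degenerate. Columns are scaled to unit norm.
#'
#' @return 13 x 3 numeric matrix with unit-norm columns.
#' @export
defaultLoadingMatrix <- function() {
  L <- matrix(0, 13, 3,
              dimnames = list(paste0("item_", 1:13),
                              paste0("component_", 1:3)))
  L[1:5, 1] <- c(0.9, 0.8, 0.85, 0.7, -0.6)
  L[6:9, 2] <- c(0.85, 0.9, -0.7, 0.75)
  L[10:13, 3] <- c(0.8, 0.85, 0.7, -0.65)
  L[6, 1] <- 0.1; L[10, 2] <- -0.08; L[1, 3] <- 0.06
  sweep(L, 2, sqrt(colSums(L^2)), "/")
}

#' Planted ground truth for a synthetic cohort
#'
#' Collects the quantities the simulators plant so that recovery can be
#' verified downstream: the latent item loading structure of the probe
#' ratings, the per-condition gradient mixing weights of the brain maps,
#' and the coefficients coupling response time to component scores or
#' coordinates.
#'
#' @param loadingMatrix 13 x 3 (items x latent components) matrix; columns
#'   are normalised to unit norm.
#' @param coordinates named list of per-condition 5-vectors of gradient
#'   mixing weights.
#' @param rtEffects named numeric vector of coefficients coupling response
#'   time to planted scores or coordinates.
#'
#' @return a list of class `PlantedTruth`.
#' @export
plantedTruth <- function(loadingMatrix = defaultLoadingMatrix(),
                         coordinates = list(
                           vigilance     = c(0.4, 0.2, -0.5, -0.1, 0.0),
                           target        = c(-0.3, -0.3, 0.3, 0.2, 0.1),
                           off_task      = c(0.2, 0.0, -0.4, 0.0, 0.0),
                           deliberate    = c(0.1, 0.0, 0.4, 0.0, 0.0),
                           verbal_self   = c(0.3, 0.1, 0.0, -0.2, 0.0)),
                         rtEffects = c(deliberate = -0.3)) {
  if (!is.matrix(loadingMatrix) || anyNA(loadingMatrix)) {
    stop("'loadingMatrix' must be a complete numeric matrix")
  }
  loadingMatrix <- sweep(loadingMatrix, 2, sqrt(colSums(loadingMatrix^2)), "/")
  if (!all(vapply(coordinates, function(w) all(is.finite(w)), logical(1)))) {
    stop("planted coordinates must be finite")
  }
  structure(list(loadingMatrix = loadingMatrix,
                 coordinates = coordinates,
                 rtEffects = rtEffects),
            class = "PlantedTruth")
}
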