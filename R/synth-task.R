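#' Simulate one task run: event schedule and parcel time series
#'
#' Generates a sustained-attention run: experimental trials of fixed
#' duration separated by jittered inter-stimulus intervals, a seeded
#' fraction of which are targets, plus `probesPerRun` experience sampling
#' probe blocks inserted after non-target trials so that every probe's
#' preceding reporting window falls entirely in a vigilance period. The
#' parcel time series is the HRF-convolved design multiplied by per-parcel
#' condition effects, plus optional linear drift and Gaussian noise.
#'
#' Probe slots are drawn uniformly among non-target trials (rejection on
#' the realised target labels rather than relabelling, so the target
#' fraction keeps its nominal expectation). Because inter-stimulus
#' intervals are at least 1.5 s, a non-target trial immediately preceding
#' the probe guarantees the 6-s window never reaches back into an earlier
#' trial.
#'
#' @param config a [simulationConfig()].
#' @param betas parcels x 6 matrix of per-parcel effects for the columns
#'   `vigilance`, `target`, `probe_window`, `thought_1..3`; a parcels x 3
#'   matrix is accepted when no probe scores are supplied.
#' @param seed integer seed.
#' @param probeScores optional probes x 3 matrix of thought-component
#'   scores attached to this run's probes (default: i.i.d. standard
#'   normal draws).
#' @param nTrials number of experimental trials; default fills the run
#'   length after reserving probe time.
#' @param driftSd standard deviation of the per-parcel linear drift slope
#'   (in signal units over the run); 0 disables drift.
#' @param noiseSd Gaussian noise standard deviation; defaults to
#'   `config$noiseSd`.
#'
#' @return list with `events` (data.frame: onset, duration, event_type,
#'   response_time), `timeseries` (volumes x parcels), `design` (the
#'   [buildDesign()] result used for generation) and `probeScores`.
#' @export
simulateTaskRun <- function(config, betas, seed, probeScores = NULL,
                            nTrials = NULL, driftSd = 0,
                            noiseSd = config$noiseSd) {
  runLength <- config$nVolumes * config$tr
  probeTime <- config$probesPerRun * config$probeDuration
  meanIsi <- mean(config$isiRange)
  if (is.null(nTrials)) {
    nTrials <- floor((runLength - probeTime - 4 * meanIsi) /
                       (config$trialDuration + meanIsi))
  }
  if (nTrials < config$probesPerRun + 1) {
    stop("infeasible schedule: run too short for the requested trials and probes")
  }
  set.seed(seed)
  isTarget <- stats::runif(nTrials) < config$targetFraction
  isi <- stats::runif(nTrials, config$isiRange[1], config$isiRange[2])
  # first trial excluded so the probe's preceding window never reaches
  # before the run start
  eligible <- which(!isTarget & seq_len(nTrials) > 1L)
  if (length(eligible) < config$probesPerRun) {
    stop("infeasible schedule: too few vigilance trials to host the probes")
  }
  probeAfter <- sort(sample(eligible, config$probesPerRun))
  onset <- 0
  ev <- vector("list", nTrials + config$probesPerRun)
  n <- 0L
  for (j in seq_len(nTrials)) {
    n <- n + 1L
    ev[[n]] <- data.frame(
      onset = onset, duration = config$trialDuration,
      event_type = if (isTarget[j]) "target" else "non_target",
      response_time = if (isTarget[j])
        stats::rlnorm(1, meanlog = log(0.6), sdlog = 0.25) else NA_real_)
    onset <- onset + config$trialDuration + isi[j]
    if (j %in% probeAfter) {
      n <- n + 1L
      ev[[n]] <- data.frame(onset = onset, duration = config$probeDuration,
                            event_type = "probe", response_time = NA_real_)
      onset <- onset + config$probeDuration
    }
  }
  events <- do.call(rbind, ev)
  if (max(events$onset + events$duration) > runLength) {
    stop("infeasible schedule: events exceed the run length")
  }
  if (is.null(probeScores)) {
    probeScores <- matrix(stats::rnorm(config$probesPerRun * 3L),
                          config$probesPerRun, 3L,
                          dimnames = list(NULL, paste0("component_", 1:3)))
  }
  design <- buildDesign(events, probeScores, tr = config$tr,
                        nVolumes = config$nVolumes,
                        probeWindow = config$probeWindow)
  X <- designMatrix(design)
  taskCols <- c("vigilance", "target", "probe_window",
                paste0("thought_", seq_len(ncol(probeScores))))
  if (!identical(design$taskColumns, taskCols)) {
    stop("degenerate schedule: missing regressors ",
         paste(setdiff(taskCols, design$taskColumns), collapse = ", "))
  }
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  if (ncol(betas) == 3L) {
    betas <- cbind(betas, matrix(0, nrow(betas), 3L))
  }
  colnames(betas) <- taskCols
  Y <- X[, taskCols, drop = FALSE] %*% t(betas)
  if (driftSd > 0) {
    tnorm <- seq(-0.5, 0.5, length.out = config$nVolumes)
    Y <- Y + outer(tnorm, stats::rnorm(nrow(betas), sd = driftSd))
  }
  if (noiseSd > 0) {
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noiseSd), nrow(Y))
  }
  colnames(Y) <- rownames(betas)
  list(events = events, timeseries = Y, design = design,
       probeScores = probeScores)
}

#' Check that no target falls in any probe's preceding window
#'
#' Scans an event table and verifies the schedule-validity constraint that
#' every experience sampling probe is preceded by a target-free window.
#'
#' @param events an event table (onset, duration, event_type).
#' @param probeWindow window length in seconds.
#' @return logical; TRUE when every probe's preceding window is clean.
#' @export
validProbeWindows <- function(events, probeWindow = 6) {
  probes <- events[events$event_type == "probe", , drop = FALSE]
  targets <- events[events$event_type == "target", , drop = FALSE]
  if (nrow(probes) == 0L) return(TRUE)
  all(vapply(probes$onset, function(on) {
    !any(targets$onset < on & targets$onset + targets$duration > on - probeWindow)
  }, logical(1)))
}
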