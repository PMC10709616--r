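#' Simulate probe-level experience sampling ratings
#'
#' Draws, for every probe, a latent 3-vector of thought-component
#' intensities (i.i.d. standard normal) and maps it to 13 item ratings on
#' the 1--10 scale: `rating = centre + scale * (L %*% z + noise)`, clipped
#' to `[1, 10]`. Ratings are continuous, matching a continuous 1--10
#' response scale. A seeded subset of participants can lose one run,
#' reproducing cohorts in which some participants contribute fewer probes.
#'
#' @param truth a [plantedTruth()] object supplying the 13 x 3 loading
#'   matrix.
#' @param config a [simulationConfig()]; `nParticipants`, `nRuns`,
#'   `probesPerRun`, `noiseSd`, `nMissingRun` and `seed` are used.
#' @param session label stored in the `session` column
#'   ("scanning", "behavioral" or "external").
#' @param centre,scaleFactor affine map from latent space to the rating
#'   scale. The defaults (5.5, 1.5) centre ratings mid-scale and keep the
#'   clipped fraction below 5% at the default noise level.
#' @param clip clip ratings to `[1, 10]` (default); disable to verify
#'   exact latent recovery.
#' @param traitSd standard deviation of an optional participant-level
#'   latent trait added to every probe's latent vector. The default 0
#'   keeps probe latents i.i.d.; positive values create stable
#'   between-participant differences, giving the run-wise score
#'   consistency (ICC) that real cohorts show.
#'
#' @return a data.frame with columns `participant`, `session`, `run`,
#'   `probe_index` and `item_1` ... `item_13`. Attributes: `latents` (the
#'   planted probe x component scores) and `clippedFraction`.
#' @export
simulateMdes <- function(truth, config, session = "scanning",
                         centre = 5.5, scaleFactor = 1.5, clip = TRUE,
                         traitSd = 0) {
  L <- truth$loadingMatrix
  if (nrow(L) != 13L) stop("the loading matrix must have 13 item rows")
  nTot <- config$nParticipants * config$nRuns * config$probesPerRun
  if (nTot == 0L) stop("empty design: no probes to simulate")
  set.seed(config$seed)
  keys <- expand.grid(probe_index = seq_len(config$probesPerRun),
                      run = seq_len(config$nRuns),
                      participant = sprintf("sub%03d",
                                            seq_len(config$nParticipants)),
                      stringsAsFactors = FALSE)[, 3:1]
  if (config$nMissingRun > 0L) {
    lose <- sample(unique(keys$participant), config$nMissingRun)
    lostRun <- sample(seq_len(config$nRuns), config$nMissingRun,
                      replace = TRUE)
    drop <- keys$participant %in% lose &
      keys$run == lostRun[match(keys$participant, lose)]
    keys <- keys[!drop, , drop = FALSE]
  }
  n <- nrow(keys)
  z <- matrix(stats::rnorm(n * ncol(L)), n, ncol(L),
              dimnames = list(NULL, colnames(L)))
  if (traitSd > 0) {
    ppl <- unique(keys$participant)
    traits <- matrix(stats::rnorm(length(ppl) * ncol(L), sd = traitSd),
                     length(ppl), ncol(L),
                     dimnames = list(ppl, colnames(L)))
    z <- z + traits[keys$participant, , drop = FALSE]
  }
  raw <- centre + scaleFactor *
    (z %*% t(L) + matrix(stats::rnorm(n * 13L, sd = config$noiseSd), n, 13L))
  clipped <- mean(raw < 1 | raw > 10)
  if (clip) raw <- pmin(pmax(raw, 1), 10)
  colnames(raw) <- paste0("item_", 1:13)
  out <- cbind(data.frame(participant = keys$participant, session = session,
                          run = keys$run, probe_index = keys$probe_index,
                          stringsAsFactors = FALSE),
               as.data.frame(raw))
  rownames(out) <- NULL
  attr(out, "latents") <- z
  attr(out, "clippedFraction") <- clipped
  out
}

#' Names of the 13 rating item columns
#' @return character vector `item_1` ... `item_13`.
#' @export
mdesItemNames <- function() paste0("item_", 1:13)
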