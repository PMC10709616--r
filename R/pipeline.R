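#' Configure an end-to-end synthetic pipeline run
#'
#' @param outputDir directory for the results bundle.
#' @param simulation a [simulationConfig()].
#' @param truth a [plantedTruth()].
#' @param k number of thought components to retain.
#' @param nBoot bootstrap iterations for the coordinate models (0
#'   disables bootstrapping).
#' @param mapNoiseSd parcel noise of the simulated subject maps.
#' @param useGLM when TRUE, subject maps are produced by the full route:
#'   simulated task runs, per-run GLM fits and fixed-effects averaging
#'   (slower); otherwise maps are simulated directly as gradient
#'   mixtures.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outputDir = tempfile("gradientspace_"),
                           simulation = simulationConfig(),
                           truth = plantedTruth(),
                           k = 3L, nBoot = 0L, mapNoiseSd = 0.5,
                           useGLM = FALSE) {
  structure(list(outputDir = outputDir, simulation = simulation,
                 truth = truth, k = as.integer(k), nBoot = as.integer(nBoot),
                 mapNoiseSd = mapNoiseSd, useGLM = isTRUE(useGLM)),
            class = "PipelineConfig")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in order on a seeded synthetic cohort: gradient
#' construction, probe-rating simulation, PCA with varimax and probe
#' scoring, subject brain maps (direct gradient mixtures, or the full
#' task-GLM route), state-space coordinates, and per-dimension mixed
#' models comparing the overt task states, at the Bonferroni-adjusted
#' alpha for the family of five dimension models. Writes a tidy
#' coordinates CSV, a model-results JSON, a text report and a YAML
#' provenance sidecar into `config$outputDir`. Identical seeds give
#' byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with `gradients`, `pca`, `scores`,
#'   `coordinates`, `models`, and the output `files`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  sim <- config$simulation
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gradients <- stage("gradients",
                     makeGradients(sim$nParcels, 5L, seed = sim$seed))
  probes <- stage("mdes", simulateMdes(config$truth, sim))
  pca <- stage("pca", fitThoughtPCA(probes, k = config$k))
  scores <- stage("scores", scoreProbes(pca, probes))
  maps <- stage("maps", if (config$useGLM) {
    simulateSubjectMapsGLM(gradients, config$truth, sim,
                           noiseSd = config$mapNoiseSd)
  } else {
    simulateBrainMaps(gradients, config$truth, sim$nParticipants,
                      noiseSd = config$mapNoiseSd, seed = sim$seed + 1L)
  })
  coords <- stage("coordinates", mapCoordinates(maps, gradients))
  overt <- coords[coords$condition %in% c("vigilance", "target"), ]
  alpha <- bonferroniAlpha(5L)
  models <- stage("infer", lapply(1:5, function(d) {
    dat <- overt[overt$dimension == d, ]
    res <- fitLMM(dat, modelSpec("rho", fixedFactors = "condition", random = "subject"))
    if (config$nBoot >= 100L) {
      res$bootstrap <- bootstrapParams(
        dat, modelSpec("rho", fixedFactors = "condition", random = "subject"),
        nIter = config$nBoot, seed = sim$seed + d)
    }
    res
  }))
  files <- list(
    coordinates = file.path(config$outputDir, "coordinates.csv"),
    models = file.path(config$outputDir, "models.json"),
    report = file.path(config$outputDir, "report.txt"),
    provenance = file.path(config$outputDir, "provenance.yaml"))
  utils::write.csv(coords, files$coordinates, row.names = FALSE,
                   quote = FALSE)
  modelJson <- lapply(seq_along(models), function(d) {
    m <- models[[d]]
    row <- m$anova[m$anova$term == "condition", ]
    c(list(dimension = d, F = row$F, NumDF = row$NumDF, DenDF = row$DenDF,
           p = row$p, alpha = alpha, significant = row$p < alpha),
      if (!is.null(m$bootstrap)) {
        b <- m$bootstrap[2, ]
        list(bootstrap_b = b$estimate, bootstrap_lower = b$lower,
             bootstrap_upper = b$upper, bootstrap_p = b$p)
      })
  })
  jsonlite::write_json(modelJson, files$models, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  sig <- vapply(modelJson, function(m) isTRUE(m$significant), logical(1))
  report <- c(
    "Synthetic neural state-space pipeline",
    sprintf("seed %d, %d participants, %d parcels", sim$seed,
            sim$nParticipants, sim$nParcels),
    sprintf("PCA: %d components, %.2f%% total variance", config$k,
            sum(varianceExplained(pca))),
    sprintf("coordinate rows: %d (%d conditions x %d subjects x 5 dimensions)",
            nrow(coords), length(maps), sim$nParticipants),
    sprintf("vigilance vs target, Bonferroni alpha %.3f:", alpha),
    vapply(seq_along(modelJson), function(d) {
      m <- modelJson[[d]]
      sprintf("  dimension %d: F(%g, %.1f) = %.2f, p = %.4g%s", d,
              m$NumDF, m$DenDF, m$F, m$p,
              if (sig[d]) "  *" else "")
    }, character(1)))
  writeLines(report, files$report)
  writeSidecar(files$provenance, config$simulation, sim$seed)
  invisible(list(gradients = gradients, pca = pca, scores = scores,
                 coordinates = coords, models = models, files = files))
}

#' Simulate subject maps through the full task-GLM route
#'
#' For each subject and run, simulates a task run whose per-parcel
#' condition effects are the planted gradient mixtures, fits the
#' first-level GLM, averages runs by fixed effects and returns the
#' subject-level z-statistic contrast maps for the five conditions.
#'
#' @param gradients a [GradientSet-class].
#' @param truth a [plantedTruth()].
#' @param sim a [simulationConfig()].
#' @param noiseSd time-series noise standard deviation.
#' @param effectScale multiplier applied to the planted mixtures when
#'   forming the per-parcel GLM effects.
#' @return named list (condition -> subjects x parcels matrix) of
#'   subject-level z maps.
#' @export
simulateSubjectMapsGLM <- function(gradients, truth, sim, noiseSd = 1,
                                   effectScale = 1) {
  Z <- scale(gradientValues(gradients))
  conditions <- c("vigilance", "target", "off_task", "deliberate",
                  "verbal_self")
  mix <- vapply(conditions,
                function(cc) as.numeric(Z %*% truth$coordinates[[cc]]),
                numeric(nParcels(gradients))) * effectScale
  # GLM effect columns: vigilance, target, probe_window (null), thoughts
  betas <- cbind(mix[, "vigilance"], mix[, "target"], 0,
                 mix[, "off_task"], mix[, "deliberate"],
                 mix[, "verbal_self"])
  rownames(betas) <- parcelIds(gradients)
  contrastCols <- c("vigilance", "target", "thought_1", "thought_2",
                    "thought_3")
  subjects <- sprintf("sub%03d", seq_len(sim$nParticipants))
  maps <- lapply(contrastCols, function(cc) {
    matrix(NA_real_, sim$nParticipants, nParcels(gradients),
           dimnames = list(subjects, parcelIds(gradients)))
  })
  names(maps) <- conditions
  for (s in seq_len(sim$nParticipants)) {
    fits <- lapply(seq_len(sim$nRuns), function(r) {
      run <- simulateTaskRun(sim, betas,
                             seed = sim$seed + 1000L * s + r,
                             noiseSd = noiseSd)
      fitParcelGLM(run$timeseries, run$design)
    })
    subj <- fixedEffectsAverage(fits)
    for (i in seq_along(conditions)) {
      maps[[i]][s, ] <- zMaps(subj)[, contrastCols[i]]
    }
  }
  maps
}
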