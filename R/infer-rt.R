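#' Multiple regression of response time on state-space predictors
#'
#' Ordinary least squares with one row per participant: z-scored response
#' time as the outcome, state-space coordinates or mean thought scores as
#' predictors, and age, gender and mean head movement as nuisance
#' covariates (numeric covariates standardized, gender sum-coded).
#' Before fitting, the outlier rule is applied: any case with
#' `|rt_z| > 2.5` has its z-score set to zero (not dropped), and the
#' number of such cases is reported. Type-III F tests per predictor are
#' computed at alpha 0.05, and a case-resampling bootstrap provides
#' percentile confidence intervals and P values.
#'
#' @param rt data.frame with columns `participant`, `rt_z`, the predictor
#'   columns and the covariates.
#' @param predictors character vector of predictor columns.
#' @param covariates nuisance covariate columns present in `rt`.
#' @param nBoot bootstrap iterations (0 disables the bootstrap).
#' @param seed bootstrap seed.
#' @return list of class `RTRegression`: `model`, `anova` (type-III F per
#'   term), `bootstrap`, `outliersZeroed` (count), `data`.
#' @export
rtRegression <- function(rt, predictors,
                         covariates = intersect(
                           c("age", "gender", "mean_movement"),
                           colnames(rt)),
                         nBoot = 1000L, seed = 1L) {
  if (anyDuplicated(rt$participant)) {
    stop("one row per participant is required")
  }
  if (length(predictors) + length(covariates) > nrow(rt) - 2L) {
    stop("overparameterized model: more predictors than participants - 2")
  }
  out <- abs(rt$rt_z) > 2.5
  rt$rt_z[out] <- 0
  factors <- predictors[!vapply(rt[predictors], is.numeric, logical(1))]
  spec <- modelSpec("rt_z",
                    fixedFactors = factors,
                    covariates = c(setdiff(predictors, factors), covariates),
                    random = NULL)
  fit <- fitLMM(rt, spec)
  boot <- if (nBoot >= 100L) bootstrapParams(rt, spec, nIter = nBoot,
                                             seed = seed) else NULL
  structure(list(model = fit$model, anova = fit$anova, bootstrap = boot,
                 outliersZeroed = sum(out), data = fit$data,
                 formula = fit$formula),
            class = "RTRegression")
}

#' @export
print.RTRegression <- function(x, ...) {
  cat("RT regression:", deparse(x$formula), "\n")
  cat(x$outliersZeroed, "outlying z-scored response times set to zero\n")
  print(x$anova, digits = 4)
  if (!is.null(x$bootstrap)) print(x$bootstrap, digits = 4)
  invisible(x)
}

#' Simulate per-participant response times coupled to planted effects
#'
#' Generates z-scored response times as a linear function of the supplied
#' per-participant predictors plus Gaussian noise, with nuisance
#' covariates (age, gender, mean movement) drawn independently: the
#' ground-truth counterpart of [rtRegression()].
#'
#' @param predictors data.frame with `participant` and numeric predictor
#'   columns.
#' @param effects named coefficients over predictor columns.
#' @param noiseSd residual standard deviation of rt_z.
#' @param seed integer seed.
#' @return data.frame ready for [rtRegression()].
#' @export
simulateRT <- function(predictors, effects, noiseSd = 0.5, seed = 1L) {
  set.seed(seed)
  n <- nrow(predictors)
  mu <- numeric(n)
  for (nm in names(effects)) mu <- mu + effects[[nm]] * predictors[[nm]]
  rt <- predictors
  rt$rt_z <- as.numeric(scale(mu + stats::rnorm(n, sd = noiseSd)))
  rt$age <- round(stats::runif(n, 18, 35))
  rt$gender <- sample(c("f", "m"), n, replace = TRUE)
  rt$mean_movement <- stats::rlnorm(n, log(0.08), 0.4)
  rt
}
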