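#' Specify a mixed or fixed-effects model
#'
#' Collects the conventions the inferential layer fixes: sum-to-zero
#' contrasts for all factors (so a 2-level factor's coefficient is half
#' the level difference and the intercept is the grand mean), REML
#' estimation, type-III F tests with Satterthwaite degrees of freedom,
#' and a participant random intercept.
#'
#' @param outcome outcome column name.
#' @param fixedFactors character vector of factor predictor columns.
#' @param covariates character vector of continuous nuisance columns;
#'   numeric covariates are standardized before entry, factor covariates
#'   (e.g. gender) are sum-coded.
#' @param random grouping column for the random intercept (NULL for an
#'   ordinary least squares fit).
#' @return a list of class `ModelSpec`.
#' @export
modelSpec <- function(outcome, fixedFactors = character(),
                      covariates = character(), random = "participant") {
  structure(list(outcome = outcome, fixedFactors = fixedFactors,
                 covariates = covariates, random = random),
            class = "ModelSpec")
}

# prepare data per the model specification: factors sum-coded, numeric
# covariates standardized; returns list(data, formula, contrasts)
prepareModelData <- function(data, spec) {
  need <- c(spec$outcome, spec$fixedFactors, spec$covariates, spec$random)
  absent <- setdiff(need, colnames(data))
  if (length(absent)) {
    stop("columns absent from the data: ", paste(absent, collapse = ", "))
  }
  keep <- !is.na(data[[spec$outcome]])
  if (!all(keep)) {
    message(sum(!keep), " rows with missing outcome dropped")
    data <- data[keep, , drop = FALSE]
  }
  contrasts <- list()
  for (f in spec$fixedFactors) {
    data[[f]] <- factor(data[[f]])
    contrasts[[f]] <- "contr.sum"
  }
  for (cv in spec$covariates) {
    if (is.numeric(data[[cv]])) {
      if (stats::sd(data[[cv]], na.rm = TRUE) > 0) {
        data[[cv]] <- as.numeric(scale(data[[cv]]))
      }
    } else {
      data[[cv]] <- factor(data[[cv]])
      contrasts[[cv]] <- "contr.sum"
    }
  }
  rhs <- c(spec$fixedFactors, spec$covariates)
  if (!length(rhs)) rhs <- "1"
  fml <- paste(spec$outcome, "~", paste(rhs, collapse = " + "))
  if (!is.null(spec$random)) {
    data[[spec$random]] <- factor(data[[spec$random]])
    if (nlevels(data[[spec$random]]) < 2L) {
      stop("random-intercept grouping needs at least 2 groups")
    }
    fml <- paste0(fml, " + (1 | ", spec$random, ")")
  }
  list(data = data, formula = stats::as.formula(fml), contrasts = contrasts)
}

#' Fit a linear mixed model with the fixed inferential conventions
#'
#' REML fit with a participant random intercept, sum-to-zero factor
#' coding, type-III F tests with Satterthwaite degrees of freedom, and
#' estimated marginal means per fixed factor at covariate means. Singular
#' fits are flagged with a warning but results are still returned.
#'
#' @param data a tidy data.frame.
#' @param spec a [modelSpec()].
#' @return a list of class `MixedModelResult` with elements `model`,
#'   `anova` (term, F, df, P), `estimates` (coefficient, SE),
#'   `emmeans` (one table per fixed factor), `formula` and `singular`.
#' @export
fitLMM <- function(data, spec) {
  prep <- prepareModelData(data, spec)
  if (is.null(spec$random)) {
    fit <- stats::lm(prep$formula, data = prep$data,
                     contrasts = if (length(prep$contrasts)) prep$contrasts else NULL)
    an <- car::Anova(fit, type = 3)
    anova <- data.frame(term = rownames(an),
                        F = an[["F value"]], NumDF = an$Df,
                        DenDF = stats::df.residual(fit),
                        p = an[["Pr(>F)"]], row.names = NULL)
    est <- summary(fit)$coefficients
    singular <- FALSE
  } else {
    fit <- lmerTest::lmer(prep$formula, data = prep$data, REML = TRUE,
                          contrasts = if (length(prep$contrasts)) prep$contrasts else NULL)
    singular <- lme4::isSingular(fit)
    if (singular) warning("singular mixed-model fit; results returned")
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    anova <- data.frame(term = rownames(an),
                        F = an[["F value"]], NumDF = an$NumDF,
                        DenDF = an$DenDF, p = an[["Pr(>F)"]],
                        row.names = NULL)
    est <- stats::coef(summary(fit))
  }
  emm <- lapply(stats::setNames(spec$fixedFactors, spec$fixedFactors),
                function(f) {
                  as.data.frame(emmeans::emmeans(
                    fit, stats::as.formula(paste("~", f)),
                    lmer.df = "satterthwaite"))
                })
  structure(list(model = fit, anova = anova,
                 estimates = data.frame(term = rownames(est),
                                        estimate = est[, "Estimate"],
                                        se = est[, "Std. Error"],
                                        row.names = NULL),
                 emmeans = emm, formula = prep$formula,
                 singular = singular, data = prep$data,
                 contrasts = if (length(prep$contrasts)) prep$contrasts else NULL, spec = spec),
            class = "MixedModelResult")
}

#' @export
print.MixedModelResult <- function(x, ...) {
  cat("Model:", deparse(x$formula), "\n")
  cat("Type-III tests (Satterthwaite df):\n")
  print(x$anova, digits = 4)
  if (!is.null(x$bootstrap)) {
    cat("Cluster bootstrap (", attr(x$bootstrap, "nIter"),
        " iterations):\n", sep = "")
    print(x$bootstrap, digits = 4)
  }
  invisible(x)
}

#' Cluster bootstrap of model coefficients
#'
#' Nonparametric case resampling at the participant level: whole
#' participants (clusters) are resampled with replacement, relabelled so
#' duplicated clusters remain distinct groups, and the model is refitted.
#' Reports the percentile 95% confidence interval per coefficient and a
#' bootstrap P value `2 * min(share <= 0, share >= 0)`, floored at
#' `2 / nIter`. For a `ModelSpec` without a random term the same scheme
#' reduces to case resampling of an OLS fit.
#'
#' @param data tidy data.frame.
#' @param spec a [modelSpec()].
#' @param nIter number of bootstrap iterations (at least 100).
#' @param seed integer seed.
#' @return data.frame of class `BootstrapParams`: term, estimate, lower,
#'   upper, p. Attributes: `nIter`, `nFailed` (non-converged resamples),
#'   `nRedrawn` (degenerate single-cluster resamples redrawn).
#' @export
bootstrapParams <- function(data, spec, nIter = 1000L, seed = 1L) {
  if (nIter < 100L) stop("'nIter' must be at least 100")
  cluster <- if (is.null(spec$random)) "participant" else spec$random
  if (!cluster %in% colnames(data)) {
    stop("cluster column '", cluster, "' absent from the data")
  }
  ids <- unique(data[[cluster]])
  rowsOf <- split(seq_len(nrow(data)), data[[cluster]])
  prep <- prepareModelData(data, spec)
  full <- refitOnce(prep, spec)
  terms <- names(full)
  set.seed(seed)
  est <- matrix(NA_real_, nIter, length(terms),
                dimnames = list(NULL, terms))
  nFailed <- 0L; nRedrawn <- 0L
  for (b in seq_len(nIter)) {
    repeat {
      pick <- sample(ids, length(ids), replace = TRUE)
      if (length(unique(pick)) > 1L || length(ids) == 1L) break
      nRedrawn <- nRedrawn + 1L
    }
    idx <- unlist(rowsOf[as.character(pick)], use.names = FALSE)
    newData <- data[idx, , drop = FALSE]
    newData[[cluster]] <- rep(seq_along(pick),
                              lengths(rowsOf[as.character(pick)]))
    co <- tryCatch(
      refitOnce(prepareModelData(newData, spec), spec),
      error = function(e) NULL)
    if (is.null(co)) nFailed <- nFailed + 1L else est[b, names(co)] <- co
  }
  ok <- stats::complete.cases(est)
  ci <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  p <- apply(est[ok, , drop = FALSE], 2, function(v) {
    max(2 * min(mean(v <= 0), mean(v >= 0)), 2 / nIter)
  })
  out <- data.frame(term = terms, estimate = full,
                    lower = ci[1, ], upper = ci[2, ], p = pmin(p, 1),
                    row.names = NULL)
  attr(out, "nIter") <- nIter
  attr(out, "nFailed") <- nFailed
  attr(out, "nRedrawn") <- nRedrawn
  class(out) <- c("BootstrapParams", "data.frame")
  out
}

# one quiet (re)fit returning the fixed-effect coefficient vector
refitOnce <- function(prep, spec) {
  if (is.null(spec$random)) {
    stats::coef(stats::lm(prep$formula, data = prep$data,
                          contrasts = if (length(prep$contrasts)) prep$contrasts else NULL))
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(prep$formula, data = prep$data, REML = TRUE,
                 contrasts = if (length(prep$contrasts)) prep$contrasts else NULL,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.conv.grad = "ignore",
                   check.conv.hess = "ignore"))))
    lme4::fixef(fit)
  }
}

#' Bonferroni-adjusted alpha for a family of models
#'
#' @param nModels number of models in the family.
#' @return `0.05 / nModels`.
#' @export
bonferroniAlpha <- function(nModels) {
  stopifnot(nModels >= 1)
  0.05 / nModels
}

#' State-by-network interaction model on network-averaged activity
#'
#' Mixed model of per-subject, per-network, per-state mean activation:
#' fixed effects for state, network and their interaction, a participant
#' random intercept, sum coding and type-III Satterthwaite F tests.
#' Pairwise state contrasts are estimated within each network and their
#' P values Bonferroni-corrected for the seven network-wise comparisons.
#'
#' @param networkMeans tidy data.frame with columns participant, state,
#'   network, value (seven networks, at least two states per subject).
#' @return list with `anova` (including the state:network interaction
#'   row), `pairwise` (per-network state contrasts with adjusted P) and
#'   the fitted `model`.
#' @export
stateByNetworkLMM <- function(networkMeans) {
  need <- c("participant", "state", "network", "value")
  absent <- setdiff(need, colnames(networkMeans))
  if (length(absent)) stop("missing columns: ", paste(absent, collapse = ", "))
  cells <- table(networkMeans$network, networkMeans$state)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty network x state cells: ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = "/", collapse = ", "))
  }
  d <- networkMeans
  d$state <- factor(d$state); d$network <- factor(d$network)
  d$participant <- factor(d$participant)
  fit <- lmerTest::lmer(value ~ state * network + (1 | participant),
                        data = d, REML = TRUE,
                        contrasts = list(state = "contr.sum",
                                        network = "contr.sum"))
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  anova <- data.frame(term = rownames(an), F = an[["F value"]],
                      NumDF = an$NumDF, DenDF = an$DenDF,
                      p = an[["Pr(>F)"]], row.names = NULL)
  emm <- emmeans::emmeans(fit, ~ state | network, lmer.df = "satterthwaite")
  pw <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise"), adjust = "none"))
  nNet <- nlevels(d$network)
  pw$p.adjusted <- pmin(1, pw$p.value * nNet)
  list(anova = anova, pairwise = pw, model = fit)
}

#' Prevalence of each thought pattern across task contexts
#'
#' One mixed model per component: the (projected) score is the outcome,
#' task context the fixed factor, probe order, day and session order the
#' nuisance covariates, with a participant random intercept. Estimated
#' marginal means per context are returned for radar or word-cloud style
#' reporting.
#'
#' @param scores projected scores carrying `participant`, `context` and
#'   the covariate columns.
#' @param covariates nuisance covariate columns.
#' @return named list, one [fitLMM()] result per score column.
#' @export
prevalenceByContext <- function(scores,
                                covariates = c("probe_order", "day", "order")) {
  counts <- table(scores$context)
  if (length(counts) < 2L) stop("at least two task contexts are required")
  if (any(counts < 2L)) {
    warning("contexts with fewer than 2 observations: ",
            paste(names(counts)[counts < 2], collapse = ", "))
  }
  sc <- grep("^score_", colnames(scores), value = TRUE)
  lapply(stats::setNames(sc, sc), function(outcome) {
    fitLMM(scores, modelSpec(outcome, fixedFactors = "context",
                             covariates = intersect(covariates,
                                                    colnames(scores))))
  })
}
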