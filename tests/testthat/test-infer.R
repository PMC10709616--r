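test_that("mixed-model conventions reproduce the paired t test", {
  d <- pairedData(24, offset = 0.4, seed = 2)
  res <- fitLMM(d, modelSpec("y", fixedFactors = "condition"))

  wide <- matrix(d$y, ncol = 2, byrow = TRUE)
  tt <- t.test(wide[, 1], wide[, 2], paired = TRUE)
  expect_equal(res$anova$F[1], unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(res$anova$DenDF[1], 23, tolerance = 1e-6)

  # sum coding: the 2-level estimate is half the level difference
  halfDiff <- (mean(wide[, 1]) - mean(wide[, 2])) / 2
  est <- res$estimates$estimate[res$estimates$term == "condition1"]
  expect_equal(est, halfDiff, tolerance = 1e-8)

  # balanced design: marginal means equal raw cell means, 2|b| apart
  emm <- res$emmeans$condition
  expect_equal(emm$emmean, unname(colMeans(wide)), tolerance = 1e-8)
  expect_equal(abs(diff(emm$emmean)), 2 * abs(est), tolerance = 1e-8)
})

test_that("null mixed models reject at the nominal rate", {
  reps <- 300
  p <- vapply(seq_len(reps), function(r) {
    d <- pairedData(57, offset = 0, seed = 1000 + r)
    fitLMM(d, modelSpec("y", fixedFactors = "condition"))$anova$p[1]
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("cluster bootstrap is seeded, floored and signal-sensitive", {
  d <- pairedData(30, offset = 5, subjectSd = 0.3, noiseSd = 0.3, seed = 3)
  spec <- modelSpec("y", fixedFactors = "condition")
  b1 <- bootstrapParams(d, spec, nIter = 200, seed = 9)
  b2 <- bootstrapParams(d, spec, nIter = 200, seed = 9)
  expect_equal(b1, b2)

  # an overwhelming planted effect: CI excludes 0, P at the floor
  row <- b1[b1$term == "condition1", ]
  expect_true(row$upper < 0 || row$lower > 0)
  expect_equal(row$p, 2 / 200)

  expect_error(bootstrapParams(d, spec, nIter = 50), "at least 100")
})

test_that("percentile intervals cover a true null about 95% of the time", {
  # case-resampling OLS route (no random term): same machinery, fast
  spec <- modelSpec("y", covariates = "x", random = NULL)
  covered <- vapply(1:100, function(r) {
    set.seed(400 + r)
    d <- data.frame(participant = seq_len(40), x = rnorm(40), y = rnorm(40))
    ci <- bootstrapParams(d, spec, nIter = 200, seed = r)
    row <- ci[ci$term == "x", ]
    row$lower <= 0 && row$upper >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 1.00)
})

test_that("bootstrap interval width shrinks with the cohort size", {
  width <- vapply(c(20, 57, 200), function(n) {
    d <- pairedData(n, offset = 0.2, seed = 7)
    b <- bootstrapParams(d, modelSpec("y", fixedFactors = "condition"),
                         nIter = 200, seed = 11)
    row <- b[b$term == "condition1", ]
    row$upper - row$lower
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("RT regression applies the outlier rule and finds planted slopes", {
  rt <- data.frame(participant = sprintf("s%02d", 1:20),
                   rt_z = c(3.0, 2.4, -2.6, rnorm(17, sd = 0.5)),
                   x = rnorm(20), age = 25, gender = rep(c("f", "m"), 10),
                   mean_movement = 0.1)
  rt$age <- rnorm(20, 25)
  rt$mean_movement <- abs(rnorm(20, 0.1, 0.02))
  rr <- rtRegression(rt, "x", nBoot = 0)
  expect_identical(rr$outliersZeroed, 2L)
  expect_equal(rr$data$rt_z[1:3], c(0, 2.4, 0))

  # power: planted negative slope recovered with CI excluding zero
  hits <- vapply(1:10, function(s) {
    pred <- data.frame(participant = sprintf("s%03d", 1:57),
                       deliberate = rnorm(57))
    sim <- simulateRT(pred, c(deliberate = -0.3), noiseSd = 0.5,
                      seed = 600 + s)
    fit <- rtRegression(sim, "deliberate", nBoot = 200, seed = s)
    row <- fit$bootstrap[fit$bootstrap$term == "deliberate", ]
    row$estimate < 0 && row$upper < 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # a predictor with no planted effect stays within 3 standard errors
  set.seed(77)
  nullRt <- data.frame(participant = sprintf("s%03d", 1:57),
                       rt_z = rnorm(57), x = rnorm(57))
  fit0 <- rtRegression(nullRt, "x", covariates = character(), nBoot = 0)
  co <- summary(fit0$model)$coefficients
  expect_lt(abs(co["x", "Estimate"]), 3 * co["x", "Std. Error"])

  expect_error(rtRegression(rt[1:4, ], c("x", "age", "mean_movement")),
               "overparameterized")
  expect_error(rtRegression(rbind(rt, rt), "x"), "one row per participant")
})

test_that("state-by-network model detects planted interactions", {
  base <- expand.grid(participant = sprintf("s%02d", 1:57),
                      state = c("vigilance", "target"),
                      network = yeoNetworkNames(),
                      stringsAsFactors = FALSE)

  # two identical states: every pairwise contrast estimate is zero
  same <- base
  vals <- rnorm(nrow(same) / 2)
  same$value <- rep(vals, 2)[order(rep(seq_len(nrow(same) / 2), 2))]
  same$value <- ave(seq_len(nrow(same)), same$participant, same$network,
                    FUN = function(i) rnorm(1))
  snSame <- suppressWarnings(stateByNetworkLMM(same))
  expect_true(all(abs(snSame$pairwise$estimate) < 1e-10))

  # planted interaction: a state difference in 2 of 7 networks
  hits <- vapply(1:10, function(s) {
    set.seed(700 + s)
    d <- base
    d$value <- rnorm(nrow(d), sd = 1) +
      ifelse(d$state == "target" &
               d$network %in% c("dorsal_attention", "frontoparietal"),
             0.8, 0)
    suppressWarnings(stateByNetworkLMM(d))$anova$p[3] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # no planted interaction: Bonferroni-adjusted rejections stay near zero
  falsePos <- vapply(1:20, function(s) {
    set.seed(800 + s)
    d <- base
    d$value <- rnorm(nrow(d))
    mean(suppressWarnings(stateByNetworkLMM(d))$pairwise$p.adjusted < 0.05)
  }, numeric(1))
  expect_lt(mean(falsePos), 0.05)

  expect_error(stateByNetworkLMM(base[base$state == "vigilance",
                                      c("participant", "state", "network")]),
               "missing columns")
})

test_that("family-wise alpha follows the models-in-family rule", {
  expect_equal(bonferroniAlpha(5), 0.01)
  expect_equal(bonferroniAlpha(1), 0.05)
  expect_equal(bonferroniAlpha(3), 0.05 / 3)
  expect_error(bonferroniAlpha(0))
})

test_that("context-prevalence models single out the affected component", {
  set.seed(55)
  d <- expand.grid(participant = sprintf("s%02d", 1:70),
                   context = paste0("task_", sprintf("%02d", 1:15)),
                   probe = 1:3, stringsAsFactors = FALSE)
  d <- d[sample(nrow(d), 2302), ]
  d$probe_order <- d$probe
  d$day <- sample(1:2, nrow(d), replace = TRUE)
  d$order <- sample(1:2, nrow(d), replace = TRUE)
  ppl <- rnorm(70)
  names(ppl) <- sprintf("s%02d", 1:70)
  d$score_1 <- rnorm(nrow(d)) + ppl[d$participant]
  d$score_2 <- rnorm(nrow(d)) + ppl[d$participant] +
    ifelse(d$context %in% c("task_01", "task_02"), 0.8, 0)

  res <- prevalenceByContext(d)
  pContext <- vapply(res, function(m) {
    m$anova$p[m$anova$term == "context"]
  }, numeric(1))
  expect_lt(pContext["score_2"], 0.05)
  expect_gt(pContext["score_1"], 0.05)
  expect_identical(nrow(res$score_2$emmeans$context), 15L)

  # identical contexts: marginal means agree within their intervals
  overlap <- res$score_1$emmeans$context
  grand <- mean(overlap$emmean)
  expect_true(all(overlap$lower.CL <= grand & grand <= overlap$upper.CL))
})
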