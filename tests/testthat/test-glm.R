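test_that("gamma HRF kernel has the canonical shape", {
  k <- gammaHRF(3)
  expect_equal(sum(k), 1, tolerance = 1e-10)
  expect_gte(length(k) * 3, 32)

  # density mode sits before the 6-s mean (gamma skew): (shape-1)*scale
  tt <- seq(0, 32, by = 0.001)
  mode <- tt[which.max(dgamma(tt, shape = 4, scale = 1.5))]
  expect_equal(mode, 4.5, tolerance = 0.01)

  # unit-sum kernel leaves a constant series constant after burn-in
  const <- rep(2.5, 100)
  conv <- stats::convolve(const, rev(gammaHRF(1)), type = "open")[1:100]
  expect_equal(conv[40:100], const[40:100], tolerance = 1e-10)
})

test_that("design construction matches a literal per-volume oracle", {
  events <- data.frame(
    onset = c(0, 5, 30, 66, 130),
    duration = c(3, 3, 3, 58.5, 3),
    event_type = c("non_target", "target", "non_target", "probe",
                   "non_target"))
  scores <- matrix(0.7, 1, 3)
  d <- buildDesign(events, scores, tr = 3, nVolumes = 60, probeWindow = 6)

  # a 6-s window before a probe at t = 66 covers exactly volumes 21-22
  raw3 <- d$raw[, "probe_window"]
  expect_equal(which(raw3 > 0), c(21, 22))
  expect_equal(unname(raw3[21:22]), c(1, 1))

  # all probe scores equal -> parametric regressors identically zero
  expect_true(all(abs(d$raw[, "thought_1"]) < 1e-12))

  # eight probes with varying scores: brute-force regressor builder
  cfg <- simulationConfig(nParticipants = 1, seed = 2)
  run <- simulateTaskRun(cfg, matrix(0, 1, 6), seed = 7, noiseSd = 0)
  sc <- run$probeScores
  probes <- run$events[run$events$event_type == "probe", ]
  centred <- scale(sc, center = TRUE, scale = FALSE)
  oracle <- numeric(cfg$nVolumes)
  for (p in seq_len(nrow(probes))) {
    vLast <- floor(probes$onset[p] / 3 + 1e-9)
    oracle[(vLast - 1):vLast] <- oracle[(vLast - 1):vLast] + centred[p, 1]
  }
  expect_equal(unname(run$design$raw[, "thought_1"]), oracle,
               tolerance = 1e-12)

  # mean-centring makes parametric EVs orthogonal to the window EV
  raw <- run$design$raw
  for (c in 1:3) {
    expect_lt(abs(sum(raw[, "probe_window"] * raw[, paste0("thought_", c)])),
              1e-10)
    expect_lt(abs(sum(raw[, paste0("thought_", c)])), 1e-10)
  }

  expect_error(buildDesign(events, matrix(0.7, 3, 3), tr = 3,
                           nVolumes = 60), "per probe")
  expect_warning(
    buildDesign(data.frame(onset = 4, duration = 30, event_type = "probe"),
                matrix(1:2, 1), tr = 3, nVolumes = 20, probeWindow = 6),
    "truncated")
})

test_that("highpass removes lines, reduces energy, passes 20-s cycles", {
  t <- (0:266) * 3
  line <- 1.7 - 0.02 * t
  expect_lt(max(abs(highpassFilter(line, 50, 3))), 1e-8)

  set.seed(4)
  wn <- rnorm(267)
  expect_lte(var(highpassFilter(wn, 50, 3)), var(wn))

  wave <- sin(2 * pi * t / 20)
  filtered <- highpassFilter(wave, 50, 3)
  mid <- 30:237  # skip edges
  attenuation <- 1 - sd(filtered[mid]) / sd(wave[mid])
  expect_lt(attenuation, 0.10)

  expect_error(highpassFilter(rnorm(2), 50, 3), "too short")
  expect_error(highpassFilter(rnorm(100), 2, 3), "exceed")
})

test_that("parcel GLM equals the normal-equations oracle", {
  set.seed(5)
  ev <- data.frame(onset = c(0, 10, 25), duration = c(3, 3, 3),
                   event_type = c("non_target", "target", "non_target"))
  d <- buildDesign(ev, NULL, tr = 3, nVolumes = 20)
  X <- designMatrix(d)
  Y <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("p", 1:6)))
  fit <- fitParcelGLM(Y, d, contrasts = list(tgt = c(target = 1)))

  oracle <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(unname(contrastEstimates(fit)[, "tgt"]),
               unname(oracle["target", ]), tolerance = 1e-10)

  # a run with no probe events drops the all-zero window regressor
  expect_identical(d$taskColumns, c("vigilance", "target"))

  # noiseless recovery through the same design
  beta <- c(intercept = 0.5, vigilance = 2, target = -1)
  Yexact <- X %*% beta
  fit2 <- fitParcelGLM(Yexact, d)
  expect_equal(unname(contrastEstimates(fit2)[1, ]),
               unname(beta[d$taskColumns]), tolerance = 1e-8)

  # null contrast: zero estimate, flagged z, no NaN propagation
  fit3 <- fitParcelGLM(Y, d, contrasts = list(null = c(target = 0)))
  expect_equal(unname(contrastEstimates(fit3)[, 1]), rep(0, 6))
  expect_true(all(is.na(zMaps(fit3))))

  # rank deficiency is an explicit, named signal
  dd <- d
  dd$matrix <- cbind(dd$matrix, dup_target = dd$matrix[, "target"])
  expect_error(fitParcelGLM(Y, dd), "dup_target")
  expect_error(fitParcelGLM(Y[1:10, ], d), "volumes")
  expect_error(expandContrasts(d, list(bad = c(intercept = 1))),
               "non-task")
})

test_that("fixed-effects averaging is inverse-variance weighting", {
  mk <- function(b, v) {
    new("ParcelGLMFit",
        beta = matrix(b, 1, 1, dimnames = list("p1", "c1")),
        variance = matrix(v, 1, 1, dimnames = list("p1", "c1")),
        z = matrix(0, 1, 1, dimnames = list("p1", "c1")),
        dof = 10, level = "run")
  }
  # identical runs: same beta, half the variance
  comb <- fixedEffectsAverage(list(mk(0.8, 0.2), mk(0.8, 0.2)))
  expect_equal(comb@beta[1, 1], 0.8)
  expect_equal(comb@variance[1, 1], 0.1)
  expect_identical(comb@level, "subject")

  # equal precision: plain average
  expect_equal(fixedEffectsAverage(list(mk(1, 1), mk(3, 1)))@beta[1, 1], 2)

  # single run passes through
  one <- fixedEffectsAverage(list(mk(1.5, 0.4)))
  expect_equal(one@beta[1, 1], 1.5)
  expect_equal(one@variance[1, 1], 0.4)

  other <- mk(1, 1)
  rownames(other@beta) <- "p2"
  expect_error(fixedEffectsAverage(list(mk(1, 1), other)), "disagree")
})

test_that("noiseless multi-run pipeline recovers truth; null z is normal", {
  cfg <- simulationConfig(nParticipants = 1, seed = 1)
  P <- 30
  set.seed(11)
  betas <- matrix(rnorm(P * 6), P, 6,
                  dimnames = list(sprintf("p%04d", 1:P), NULL))
  fits <- lapply(1:3, function(r) {
    run <- simulateTaskRun(cfg, betas, seed = 50 + r, noiseSd = 0)
    fitParcelGLM(run$timeseries, run$design)
  })
  subj <- fixedEffectsAverage(fits)
  expect_lt(max(abs(contrastEstimates(subj) - betas)), 1e-6)

  # null contrasts over 200 noisy parcels are standard normal
  nullRun <- simulateTaskRun(
    simulationConfig(nParticipants = 1, nParcels = 200, seed = 2),
    matrix(0, 200, 6, dimnames = list(sprintf("p%04d", 1:200), NULL)),
    seed = 99, noiseSd = 1)
  zf <- fitParcelGLM(nullRun$timeseries, nullRun$design)
  ks <- ks.test(zMaps(zf)[, "target"], "pnorm")
  expect_gt(ks$p.value, 0.01)
})
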