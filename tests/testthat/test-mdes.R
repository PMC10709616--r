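scanProbes <- simulateMdes(tinyTruth,
                           simulationConfig(nParticipants = 30, nRuns = 3,
                                            probesPerRun = 8, seed = 21))
scanPCA <- fitThoughtPCA(scanProbes, 3)

test_that("PCA standardizes items, rotates and keeps invariants", {
  # one component: rotation is the identity, loadings equal the first
  # principal axis of the correlation matrix
  p1 <- fitThoughtPCA(scanProbes, 1)
  X <- as.matrix(scanProbes[, mdesItemNames()])
  ei <- eigen(cor(X), symmetric = TRUE)
  axis <- ei$vectors[, 1] * sqrt(ei$values[1])
  axis <- axis * sign(axis[which.max(abs(axis))])
  expect_equal(unname(componentLoadings(p1)[, 1]), axis, tolerance = 1e-10)

  # rotation preserves per-item communalities and retained variance
  A <- ei$vectors[, 1:3] %*% diag(sqrt(ei$values[1:3]))
  L <- componentLoadings(scanPCA)
  expect_equal(rowSums(L^2), unname(rowSums(A^2)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(varianceExplained(scanPCA)),
               100 * sum(ei$values[1:3]) / 13, tolerance = 1e-8)

  # components ordered by descending rotated variance, anchored positive
  expect_true(all(diff(colSums(L^2)) <= 1e-12))
  for (j in 1:3) expect_gt(L[which.max(abs(L[, j])), j], 0)

  expect_error(fitThoughtPCA(scanProbes, 0), "between 1 and 13")
  expect_error(fitThoughtPCA(scanProbes, 14), "between 1 and 13")
  flat <- scanProbes
  flat$item_7 <- 5
  expect_error(fitThoughtPCA(flat, 3), "item_7")
})

test_that("recovery holds at study scale and moderate noise", {
  cfg <- simulationConfig(nParticipants = 62, nRuns = 3, probesPerRun = 8,
                          nMissingRun = 4, noiseSd = 0.5, seed = 1)
  probes <- simulateMdes(tinyTruth, cfg)
  expect_identical(nrow(probes), 1456L)
  pca <- fitThoughtPCA(probes, 3)
  phi <- tuckerCongruence(tinyTruth$loadingMatrix, componentLoadings(pca))
  expect_true(all(phi >= 0.95))
})

test_that("probe scoring is the dot product on the training scale", {
  # a probe at the item means scores zero on every component
  atMean <- as.data.frame(as.list(scanPCA@itemMeans))
  expect_equal(unname(as.matrix(scoreProbes(scanPCA, atMean))),
               matrix(0, 1, 3), tolerance = 1e-12)

  # standardized items all equal 1 -> score is the loading column sum
  oneSd <- as.data.frame(as.list(scanPCA@itemMeans + scanPCA@itemSds))
  expect_equal(unname(as.matrix(scoreProbes(scanPCA, oneSd))),
               matrix(colSums(componentLoadings(scanPCA)), 1),
               tolerance = 1e-10)

  # scoring the training set twice is exactly idempotent
  s1 <- scoreProbes(scanPCA, scanProbes)
  s2 <- scoreProbes(scanPCA, scanProbes)
  expect_equal(s1, s2, tolerance = 1e-12)

  broken <- scanProbes[, setdiff(colnames(scanProbes), "item_13")]
  expect_error(scoreProbes(scanPCA, broken), "item_13")
})

test_that("external projection uses the training scale, never its own", {
  # identical data -> identical scores
  expect_equal(projectExternal(scanPCA, scanProbes),
               scoreProbes(scanPCA, scanProbes), tolerance = 1e-12)

  # shifting item means shifts scores by loadings . (shift / sd)
  shift <- seq(0.1, 1.3, by = 0.1)
  shifted <- scanProbes
  for (i in 1:13) {
    shifted[[paste0("item_", i)]] <- shifted[[paste0("item_", i)]] + shift[i]
  }
  base <- as.matrix(scoreProbes(scanPCA, scanProbes)[, 5:7])
  proj <- as.matrix(projectExternal(scanPCA, shifted)[, 5:7])
  expected <- drop((shift / scanPCA@itemSds) %*% componentLoadings(scanPCA))
  expect_equal(proj - base,
               matrix(expected, nrow(base), 3, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("participant means aggregate probes across runs", {
  sc <- data.frame(participant = c("a", "a", "a", "b"),
                   run = c(1, 1, 2, 1),
                   score_1 = c(1, 2, 3, 5))
  pm <- participantMeans(sc)
  expect_equal(pm$score_1, c(2, 5))

  # permutation invariance
  perm <- sc[c(3, 1, 4, 2), ]
  expect_equal(participantMeans(perm)$score_1, pm$score_1)

  # a participant with a dropped run is averaged over the 16 remaining
  cfg <- simulationConfig(nParticipants = 10, nRuns = 3, probesPerRun = 8,
                          nMissingRun = 1, seed = 5)
  scores <- scoreProbes(scanPCA, simulateMdes(tinyTruth, cfg))
  nProbes <- table(scores$participant)
  short <- names(nProbes)[nProbes == 16]
  expect_length(short, 1)
  byHand <- mean(scores$score_1[scores$participant == short])
  pm2 <- participantMeans(scores)
  expect_equal(pm2$score_1[pm2$participant == short], byHand)
})

test_that("consistency ICC matches a mean-squares oracle and is 1 for
           duplicated runs", {
  # duplicated runs: zero within-subject variance
  dup <- data.frame(participant = rep(c("a", "b", "c"), each = 2),
                    run = rep(1:2, 3),
                    score_1 = rep(c(0.3, -1.2, 0.8), each = 2))
  expect_equal(iccConsistency(dup, 1), 1)

  # 3x3 toy table against a hand ANOVA decomposition
  M <- matrix(c(1.0, 1.4, 1.1,
                -0.2, 0.1, 0.0,
                0.6, 0.9, 1.0), 3, 3, byrow = TRUE)
  toy <- data.frame(participant = rep(letters[1:3], each = 3),
                    run = rep(1:3, 3), score_1 = as.numeric(t(M)))
  n <- 3; k <- 3; grand <- mean(M)
  msr <- k * sum((rowMeans(M) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(M) - grand)^2) / (k - 1)
  mse <- (sum((M - grand)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  expect_equal(iccConsistency(toy, 1), (msr - mse) / (msr + (k - 1) * mse),
               tolerance = 1e-12)

  expect_error(iccConsistency(dup[dup$participant == "a", ], 1),
               "two participants")
})

test_that("ICC falls as within-participant noise grows", {
  meanICC <- vapply(c(0.3, 1, 3), function(noise) {
    mean(vapply(1:20, function(r) {
      cfg <- simulationConfig(nParticipants = 20, nRuns = 3,
                              probesPerRun = 4, noiseSd = noise,
                              seed = 100 + r)
      probes <- simulateMdes(tinyTruth, cfg, traitSd = 1)
      sc <- scoreProbes(fitThoughtPCA(probes, 3), probes)
      iccConsistency(sc, 1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanICC) < 0))
})
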