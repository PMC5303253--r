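test_that("identical class distributions with equal priors give posterior 0.5", {
  model <- fitBayesHeg(fixHegRscu, fixHegRscu, priorHeg = 0.5)
  # any in-gate gene: use the HEG members themselves
  for (i in 1:5) {
    expect_equal(hegp(fixHegRscu[i, ], model), 0.5, tolerance = 1e-12)
  }
})

test_that("posterior matches a direct (non-log) evaluation on a hand-set toy", {
  # two informative features, the other 57 identical across classes
  model <- fitBayesHeg(fixHegRscu, rscuMatrix(fixBg), priorHeg = 0.4)
  set.seed(11)
  for (i in 1:5) {
    r <- fixHegRscu[i, ] + rnorm(59, 0, 0.05)
    gauss <- function(x, mu, sd) exp(-(x - mu)^2 / (2 * sd^2)) / (sd * sqrt(2 * pi))
    qH <- 0.4 * prod(gauss(r, model@hegMean, model@hegSd))
    qB <- 0.6 * prod(gauss(r, model@bgMean, model@bgSd))
    expected <- if (qH + qB > 0) qH / (qH + qB) else NA_real_
    p <- pcaScores(r, model)
    inGate <- all(p >= model@pcaBounds[, 1] & p <= model@pcaBounds[, 2])
    got <- hegp(r, model)
    if (inGate && is.finite(expected)) {
      expect_equal(got, expected, tolerance = 1e-9)
    } else if (!inGate) {
      expect_identical(got, 0)
    }
  }
})

test_that("every HEG training member passes its own PCA gate", {
  for (i in seq_len(nrow(fixHegRscu))) {
    p <- pcaScores(fixHegRscu[i, ], fixBayes)
    expect_true(all(p >= fixBayes@pcaBounds[, 1] &
                    p <= fixBayes@pcaBounds[, 2]))
    expect_gt(hegp(fixHegRscu[i, ], fixBayes), 0)
  }
})

test_that("the PCA gate forces 0 outside the box regardless of likelihoods", {
  # push a gene far along PC1, beyond the HEG score range
  far <- fixBayes@pcaCenter + 10 * (abs(fixBayes@pcaBounds[1, 2]) + 1) *
    fixBayes@pcaRotation[, 1]
  expect_identical(hegp(far, fixBayes), 0)
  # any background gene that leaves the box scores exactly 0, not merely small
  for (g in fixBg) {
    p <- pcaScores(g, fixBayes)
    if (any(p < fixBayes@pcaBounds[, 1] | p > fixBayes@pcaBounds[, 2])) {
      expect_identical(hegp(g, fixBayes), 0)
    }
  }
})

test_that("hegp stays within [0,1] and never over/underflows in log space", {
  set.seed(12)
  for (i in 1:20) {
    g <- randomSynonymousGene(randomProtein(30))
    v <- hegp(g, fixBayes)
    expect_true(is.finite(v) && v >= 0 && v <= 1)
  }
})

test_that("fitBayesHeg validates its inputs", {
  expect_error(fitBayesHeg(fixHegRscu[1:2, ], fixHegRscu), "at least 3")
  expect_error(fitBayesHeg(fixHegRscu, fixHegRscu[0, , drop = FALSE]), "empty")
  expect_error(fitBayesHeg(fixHegRscu, fixHegRscu, priorHeg = 1.2), "prior")
})

test_that("PCA components are orthonormal and member scores sit inside the bounds", {
  rot <- fixBayes@pcaRotation
  expect_equal(crossprod(rot), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  scores <- t(apply(fixHegRscu, 1, pcaScores, model = fixBayes))
  expect_true(all(scores[, 1] >= fixBayes@pcaBounds[1, 1] &
                  scores[, 1] <= fixBayes@pcaBounds[1, 2]))
  expect_true(all(scores[, 2] >= fixBayes@pcaBounds[2, 1] &
                  scores[, 2] <= fixBayes@pcaBounds[2, 2]))
})

test_that("raw distance equals a naive double-loop oracle on random vectors", {
  set.seed(13)
  H <- matrix(runif(20 * 59, 0, 3), 20, 59)
  for (i in 1:5) {
    r <- runif(59, 0, 3)
    naive <- 0
    for (j in seq_len(nrow(H))) {
      s <- 0
      for (k in 1:59) s <- s + (r[k] - H[j, k])^2
      naive <- naive + sqrt(s)
    }
    naive <- naive / nrow(H)
    expect_equal(dhegRaw(r, H), naive, tolerance = 1e-12)
  }
})

test_that("raw distance closed forms: self-distance 0; two-member average", {
  h1 <- rscu(fixHeg[[1]])
  expect_identical(dhegRaw(h1, matrix(h1, 1, 59)), 0)
  # ||h1 - h2|| = 2 by construction
  h2 <- h1
  h2[1] <- h1[1] + 2
  H <- rbind(h1, h2)
  expect_equal(dhegRaw(h1, H), (0 + 2) / 2, tolerance = 1e-12)
})

test_that("normalization endpoints: dMin maps to 1, dMax to 0, midpoint to 0.5", {
  cal <- dhegCalibration(4, 17)
  origin <- matrix(0, 1, 59)
  atDist <- function(d) {
    v <- numeric(59)
    v[1] <- d
    v
  }
  expect_identical(dheg(atDist(4), origin, cal), 1)
  expect_identical(dheg(atDist(17), origin, cal), 0)
  expect_equal(dheg(atDist(10.5), origin, cal), 0.5)
  # clipping outside the calibration range
  expect_identical(dheg(atDist(20), origin, cal), 0)
  expect_identical(dheg(atDist(1), origin, cal), 1)
})

test_that("degenerate calibration is rejected", {
  expect_error(dhegCalibration(4, 4), "strictly below")
  expect_error(calibrateDheg(fixHeg, nSamples = 1), "at least 2")
})

test_that("mean-of-norms distance is 1-Lipschitz in the query vector", {
  set.seed(14)
  for (i in 1:10) {
    r1 <- runif(59, 0, 3)
    r2 <- runif(59, 0, 3)
    lhs <- abs(dhegRaw(r1, fixHegRscu) - dhegRaw(r2, fixHegRscu))
    expect_lte(lhs, sqrt(sum((r1 - r2)^2)) + 1e-12)
  }
})

test_that("calibration is deterministic, brackets its samples, and only widens", {
  c1 <- calibrateDheg(fixHeg, nSamples = 30, seed = 21, lengthRange = c(60, 100))
  c2 <- calibrateDheg(fixHeg, nSamples = 30, seed = 21, lengthRange = c(60, 100))
  expect_identical(c1@dMin, c2@dMin)
  expect_identical(c1@dMax, c2@dMax)
  # HEG members' own distances are inside the bracket
  for (i in 1:5) {
    d <- dhegRaw(fixHegRscu[i, ], fixHegRscu)
    expect_gte(d, c1@dMin)
    expect_lte(d, c1@dMax)
  }
  c3 <- calibrateDheg(fixHeg, nSamples = 60, seed = 21, lengthRange = c(60, 100))
  expect_lte(c3@dMin, c1@dMin)
  expect_gte(c3@dMax, c1@dMax)
})
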