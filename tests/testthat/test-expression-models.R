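test_that("hidden-layer sizing matches the closed form", {
  expect_identical(huangSizes(3), c(m = 5L, n = 2L))
  expect_identical(huangSizes(12), c(m = 10L, n = 4L))
  expect_identical(huangSizes(73), c(m = 25L, n = 10L))
  expect_identical(huangSizes(1), c(m = 3L, n = 1L))
  expect_error(huangSizes(0), "at least 1")
})

test_that("forward pass reproduces the hand-evaluated 1-1-1 network", {
  model <- nnModel(W1 = matrix(c(1, 1, 0), 1, 3),
                   W2 = matrix(c(1, 0), 1, 2),
                   Wout = matrix(c(1, 0), 1, 2))
  o1 <- 0.5 + 0.5
  h1 <- 1 / (1 + exp(-o1))
  h2 <- 1 / (1 + exp(-h1))
  expect_equal(nnForward(model, 0.5, 0.5), h2, tolerance = 1e-12)
  expect_equal(h2, 0.67504, tolerance = 1e-5)
})

test_that("a zero-weight network outputs exactly 0", {
  model <- nnModel(W1 = matrix(0, 4, 3), W2 = matrix(0, 2, 5),
                   Wout = matrix(0, 1, 3))
  expect_identical(nnForward(model, 0.3, 0.6), 0)
})

test_that("forward pass is deterministic and vectorized consistently", {
  set.seed(31)
  model <- nnModel(W1 = matrix(rnorm(9), 3, 3), W2 = matrix(rnorm(8), 2, 4),
                   Wout = matrix(rnorm(3), 1, 3),
                   xCenter = c(0.5, 0.5), xScale = c(0.2, 0.1),
                   yCenter = 50, yScale = 20)
  cai <- c(0.2, 0.7, 0.9)
  gc <- c(0.4, 0.5, 0.6)
  vec <- nnForward(model, cai, gc)
  one <- vapply(1:3, function(i) nnForward(model, cai[i], gc[i]), numeric(1))
  expect_identical(vec, one)
  expect_identical(vec, nnForward(model, cai, gc))
})

test_that("model container shapes are validated", {
  expect_error(nnModel(matrix(0, 2, 2), matrix(0, 1, 3), matrix(0, 1, 2)),
               "3 columns")
  expect_error(nnModel(matrix(0, 2, 3), matrix(0, 1, 2), matrix(0, 1, 2)),
               "m \\+ 1")
})

test_that("an ensemble of identical members equals the single member", {
  model <- nnModel(W1 = matrix(0.3, 2, 3), W2 = matrix(-0.2, 2, 3),
                   Wout = matrix(0.5, 1, 3))
  cors <- data.frame(repeatId = 1:3, train = 1, validation = 1, test = 1)
  ens <- new("ExpressionEnsemble", members = list(model, model, model),
             restriction = "none", threshold = 0.75, cors = cors,
             m = 2L, n = 2L, scorers = list())
  expect_equal(predictEnsemble(ens, 0.6, 0.5), nnForward(model, 0.6, 0.5),
               tolerance = 1e-14)
})

test_that("the split protocol gives 30/21/49 at N = 100", {
  set.seed(1)
  sp <- hegopt:::.splitIndices(100)
  expect_length(sp$test, 30)
  expect_length(sp$validation, 21)
  expect_length(sp$train, 49)
  expect_identical(sort(c(sp$test, sp$validation, sp$train)), 1:100)
})

test_that("ensemble training is deterministic under a fixed seed", {
  genes <- makeSkewGradientSet(genesPerSkew = 6, lengthRange = c(60, 100),
                               seed = 5, profileSeed = 1)
  tbl <- makeExpressionTable(synthYieldSurface("gaussian-bump", noiseSd = 5),
                             genes, fixRef, seed = 6)
  e1 <- trainEnsemble(tbl, repeats = 3, seed = 42,
                      control = list(epochs = 200))
  e2 <- trainEnsemble(tbl, repeats = 3, seed = 42,
                      control = list(epochs = 200))
  expect_identical(correlationRecords(e1), correlationRecords(e2))
  expect_identical(e1@members[[1]]@W1, e2@members[[1]]@W1)
})

test_that("a noiseless smooth yield surface is learned to high test correlation", {
  genes <- makeSkewGradientSet(genesPerSkew = 34, lengthRange = c(80, 150),
                               seed = 5, profileSeed = 1)
  tbl <- makeExpressionTable(synthYieldSurface("gaussian-bump", noiseSd = 0),
                             genes, fixRef, seed = 6)
  ens <- trainEnsemble(tbl, repeats = 5, seed = 7)
  expect_gt(median(correlationRecords(ens)$test), 0.95)
})

test_that("training rejects degenerate expression tables", {
  tbl <- data.frame(cai = runif(12), gc = runif(12), yield_mgL = 5)
  expect_error(trainEnsemble(tbl, repeats = 2, seed = 1), "zero variance")
  small <- data.frame(cai = runif(5), gc = runif(5), yield_mgL = runif(5))
  expect_error(trainEnsemble(small, repeats = 2, seed = 1), "at least 10")
})

test_that("restriction gating returns the similarity score below threshold", {
  model <- nnModel(W1 = matrix(0, 1, 3), W2 = matrix(0, 1, 2),
                   Wout = matrix(c(0, 100), 1, 2))  # constant high prediction
  cors <- data.frame(repeatId = 1L, train = 1, validation = 1, test = 1)
  ens <- new("ExpressionEnsemble", members = list(model),
             restriction = "none", threshold = 0.75, cors = cors,
             m = 1L, n = 1L, scorers = list())
  gBg <- fixBg[[1]]   # dissimilar to the reference: hegp far below threshold
  gHeg <- fixHeg[[1]] # resembles the reference: high dheg
  ensP <- attachScorers(ens, "HEGP", bayes = fixBayes)
  sP <- hegp(gBg, fixBayes)
  expect_lt(sP, 0.75)
  expect_identical(predictFitness(ensP, gBg, fixRef), sP)
  ensD <- attachScorers(ens, "DHEG", hegRscu = fixHegRscu, cal = fixCal)
  sHeg <- dheg(gHeg, fixHegRscu, fixCal)
  if (sHeg >= 0.75) {
    expect_equal(predictFitness(ensD, gHeg, fixRef), 100, tolerance = 1e-9)
  }
  sBg <- dheg(gBg, fixHegRscu, fixCal)
  expect_lt(sBg, 0.75)
  expect_equal(predictFitness(ensD, gBg, fixRef), sBg)
  expect_lt(predictFitness(ensD, gBg, fixRef), 0.75)  # gated output < threshold
  # unrestricted fitness equals the ensemble mean
  expect_equal(predictFitness(ens, gBg, fixRef),
               predictEnsemble(ens, cai(gBg, fixRef), gcContent(gBg)))
  # missing scorers are an error
  expect_error(predictFitness(attachScorers(ens, "HEGP"), gBg, fixRef),
               "BayesHegModel")
})

test_that("linear model recovers a noiseless linear surface to 1e-9", {
  pts <- data.frame(cai = c(0.1, 0.3, 0.5, 0.8, 0.9),
                    gc = c(0.5, 0.2, 0.9, 0.4, 0.7))
  pts$yield_mgL <- 2 * pts$cai + 1 * pts$gc + 0.1
  lin <- fitLinear(pts)
  expect_equal(lin@w1, 2, tolerance = 1e-9)
  expect_equal(lin@w2, 1, tolerance = 1e-9)
  expect_equal(lin@intercept, 0.1, tolerance = 1e-9)
})

test_that("constant yields give zero slopes and the constant intercept", {
  pts <- data.frame(cai = c(0.1, 0.4, 0.7, 0.9), gc = c(0.3, 0.6, 0.2, 0.8),
                    yield_mgL = 5)
  lin <- fitLinear(pts)
  expect_equal(c(lin@w1, lin@w2, lin@intercept), c(0, 0, 5), tolerance = 1e-9)
})

test_that("least-squares fit beats 100 random coefficient perturbations", {
  set.seed(33)
  pts <- data.frame(cai = runif(30), gc = runif(30))
  pts$yield_mgL <- 50 * pts$cai + 10 * pts$gc + rnorm(30, 0, 3)
  lin <- fitLinear(pts)
  rss <- function(w1, w2, b) {
    sum((pts$yield_mgL - (w1 * pts$cai + w2 * pts$gc + b))^2)
  }
  rss0 <- rss(lin@w1, lin@w2, lin@intercept)
  for (i in 1:100) {
    d <- rnorm(3, 0, 0.5)
    expect_lte(rss0, rss(lin@w1 + d[1], lin@w2 + d[2], lin@intercept + d[3]))
  }
})

test_that("rank-deficient designs are rejected", {
  pts <- data.frame(cai = c(0.2, 0.4, 0.6, 0.8), gc = c(0.2, 0.4, 0.6, 0.8))
  pts$yield_mgL <- pts$cai * 10
  expect_error(fitLinear(pts), "rank")
  expect_error(fitLinear(pts[1:2, ]), "at least 3")
})

test_that("model JSON container round-trips the ensemble and baseline", {
  genes <- makeSkewGradientSet(genesPerSkew = 4, lengthRange = c(60, 90),
                               seed = 5, profileSeed = 1)
  tbl <- makeExpressionTable(synthYieldSurface("linear", noiseSd = 2),
                             genes, fixRef, seed = 6)
  ens <- trainEnsemble(tbl, repeats = 2, seed = 9,
                       control = list(epochs = 100))
  lin <- fitLinear(tbl)
  path <- withr::local_tempfile(fileext = ".json")
  saveModelJson(ens, lin, path)
  back <- loadModelJson(path)
  expect_equal(predictEnsemble(back$ensemble, 0.6, 0.5),
               predictEnsemble(ens, 0.6, 0.5), tolerance = 1e-12)
  expect_equal(back$linear@w1, lin@w1, tolerance = 1e-12)
  expect_equal(correlationRecords(back$ensemble)$test,
               correlationRecords(ens)$test, tolerance = 1e-12)
})
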