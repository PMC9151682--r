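test_that("the reference protocol partitions 750 samples as 52/473/225", {
  y <- rep(1:15, each = 50)
  cfg <- alConfig(seed = 4)
  st <- initPools(y, cfg)
  expect_length(st@labeledIdx, 52)
  expect_length(st@unlabeledIdx, 473)
  expect_length(st@testIdx, 225)
  ## disjoint and exhaustive
  expect_setequal(c(st@labeledIdx, st@unlabeledIdx, st@testIdx), 1:750)
  ## at least one initial label per class
  expect_setequal(unique(y[st@labeledIdx]), 1:15)
  ## stratified test split: 15 per class
  expect_equal(as.vector(table(y[st@testIdx])), rep(15, 15))
  ## determinism
  st2 <- initPools(y, cfg)
  expect_identical(st@labeledIdx, st2@labeledIdx)
  expect_identical(st@testIdx, st2@testIdx)
})

test_that("infeasible pool configurations are rejected", {
  y <- rep(1:3, each = 10)
  expect_error(initPools(y, alConfig(initialLabeled = 2)), ">=")
  expect_error(initPools(y, alConfig(initialLabeled = 21, budget = 0,
                                     testFraction = 0.3)),
               "no unlabeled pool")
  expect_error(alConfig(budget = 60, nIterations = 7), "divisible")
})

test_that("uncertainty scores behave at the extremes and sort correctly", {
  oneHot <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(leastConfidence(oneHot), 0)
  expect_equal(entropyScore(oneHot), 0)
  unif <- matrix(1 / 15, 1, 15)
  expect_equal(leastConfidence(unif), 1 - 1 / 15)
  expect_equal(entropyScore(unif), log(15))
  ## batch top-m selection equals the full-sort oracle with index ties
  set.seed(34)
  p <- matrix(runif(40 * 3), 40, 3)
  p <- p / rowSums(p)
  s <- leastConfidence(p)
  pick <- order(-s, seq_along(s))[1:5]
  oracle <- head(order(s, decreasing = TRUE), 5)
  expect_equal(sort(s[pick]), sort(s[oracle]))
  ## entropy equals direct summation
  expect_equal(entropyScore(p), -rowSums(p * log(p)))
})

test_that("the EAL loop keeps its bookkeeping invariants", {
  x <- tinySpectra(3, 30, 12, seed = 41)
  y <- classLabels(x)
  X <- reflectance(x)
  cfg <- alConfig(initialLabeled = 6, budget = 20, nIterations = 5,
                  testFraction = 0.3, seed = 2)
  st <- runEAL(X, y, cfg,
               learnerBoost(boostParams(nRounds = 20, seed = 1)))
  n <- length(y)
  expect_length(st@history, 5)
  expect_length(st@labeledIdx, 6 + 20)
  ## partition conserved, no sample queried twice
  expect_setequal(c(st@labeledIdx, st@unlabeledIdx, st@testIdx), seq_len(n))
  queried <- unlist(lapply(st@history, `[[`, "queried"))
  expect_length(queried, 20)
  expect_false(anyDuplicated(queried) > 0)
  expect_true(all(queried %in% st@labeledIdx))
  ## labeled set grows by exactly batchSize per iteration
  expect_true(all(lengths(lapply(st@history, `[[`, "queried")) == 4))
})

test_that("budget zero degenerates to one passive evaluation", {
  x <- tinySpectra(3, 20, 10, seed = 42)
  cfg <- alConfig(initialLabeled = 9, budget = 0, nIterations = 1,
                  testFraction = 0.3, seed = 3)
  st <- runEAL(reflectance(x), classLabels(x), cfg,
               learnerBoost(boostParams(nRounds = 15, seed = 1)))
  expect_length(st@history, 1)
  expect_s4_class(finalReport(st), "MetricsReport")
  expect_length(st@history[[1]]$queried, 0)
})

test_that("a uniform-probability learner queries the lowest pool indices", {
  uniformLearner <- list(
    name = "uniform",
    fit = function(X, y, seed) sort(unique(y)),
    predictProba = function(model, X, nClasses)
      matrix(1 / nClasses, nrow(X), nClasses))
  y <- rep(1:3, each = 20)
  X <- matrix(rnorm(120), 60, 2)
  cfg <- alConfig(initialLabeled = 6, budget = 10, nIterations = 2,
                  testFraction = 0.2, seed = 7)
  st <- runEAL(X, y, cfg, uniformLearner)
  pools <- initPools(y, cfg)
  expect_identical(st@history[[1]]$queried, head(pools@unlabeledIdx, 5))
  ## second batch: next five lowest of the remaining pool
  expect_identical(st@history[[2]]$queried,
                   head(setdiff(pools@unlabeledIdx,
                                st@history[[1]]$queried), 5))
  ## deterministic function of the seed and tie-break
  st2 <- runEAL(X, y, cfg, uniformLearner)
  expect_identical(st@labeledIdx, st2@labeledIdx)
})

test_that("method comparison shares pools and label budgets per run", {
  x <- tinySpectra(3, 25, 10, seed = 43)
  y <- classLabels(x)
  X <- reflectance(x)
  cfg <- alConfig(initialLabeled = 6, budget = 12, nIterations = 3,
                  testFraction = 0.3, nRuns = 2, seed = 11)
  cmp <- runComparison(
    X, y, cfg,
    activeLearners = list(EAL = learnerBoost(boostParams(nRounds = 20)),
                          AL = learnerLogistic()))
  expect_setequal(rownames(cmp), c("EAL", "AL", "RF", "DT"))
  expect_named(cmp, c("oa", "kappa", "macro", "recall", "f1"))
  expect_true(all(cmp$oa >= 0 & cmp$oa <= 1))
})

test_that("every method hits the ceiling on perfectly separable data", {
  ## zero-noise zero-scatter: classes are single points
  p <- makeClassProfiles(3, 12, seed = 44)
  x <- simulateSpectra(p, 25, scatterModel(0, c(1, 1), 0), seed = 44)
  ## add microscopic jitter so learners see nonconstant features
  set.seed(45)
  R <- reflectance(x) + matrix(rnorm(75 * 12, 0, 1e-6), 75, 12)
  cfg <- alConfig(initialLabeled = 9, budget = 12, nIterations = 3,
                  testFraction = 0.3, nRuns = 1, seed = 13)
  cmp <- runComparison(R, classLabels(x), cfg,
                       activeLearners = list(
                         EAL = learnerBoost(boostParams(
                           nRounds = 30, minChildWeight = 0))))
  expect_true(all(cmp$oa == 1))
})

test_that("annotator label noise corrupts only queried labels", {
  x <- tinySpectra(3, 25, 10, seed = 46)
  y <- classLabels(x)
  cfg <- alConfig(initialLabeled = 6, budget = 30, nIterations = 3,
                  testFraction = 0.2, seed = 21)
  ## flip every queried label: the learner sees wrong classes, the
  ## evaluation ground truth stays intact
  recorded <- new.env()
  spyLearner <- list(
    name = "spy",
    fit = function(X, y, seed) {
      recorded$last <- y
      sort(unique(y))
    },
    predictProba = function(model, X, nClasses)
      matrix(1 / nClasses, nrow(X), nClasses))
  st <- runEAL(reflectance(x), y, cfg, spyLearner, labelNoise = 1)
  queried <- unlist(lapply(st@history, `[[`, "queried"))
  fed <- recorded$last                   # labels of the final fit
  trueLab <- y[st@labeledIdx]
  wrong <- fed != trueLab
  ## exactly the queried samples are wrong
  expect_setequal(st@labeledIdx[wrong], queried)
})
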