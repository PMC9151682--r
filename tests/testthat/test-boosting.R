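test_that("softmax gradients and Hessians are correct", {
  ## symmetric case by hand
  gh <- softmaxGradHess(1L, matrix(0, 1, 3))
  expect_equal(as.vector(gh$g), c(1 / 3 - 1, 1 / 3, 1 / 3))
  expect_equal(as.vector(gh$h), rep(2 / 9, 3))
  ## certain prediction: g, h -> 0
  gh2 <- softmaxGradHess(2L, matrix(c(-50, 50, -50), 1, 3))
  expect_lt(max(abs(gh2$g)), 1e-30)
  expect_lt(max(abs(gh2$h)), 1e-30)
  ## finite-difference oracle on random scores
  set.seed(23)
  S <- matrix(rnorm(5 * 4), 5, 4)
  y <- sample(4, 5, replace = TRUE)
  loss <- function(S) {
    lse <- log(rowSums(exp(S)))
    sum(lse - S[cbind(seq_len(5), y)])
  }
  gh3 <- softmaxGradHess(y, S)
  eps <- 1e-5
  epsH <- 1e-4  # second differences need a larger step against roundoff
  for (i in 1:5) for (c_ in 1:4) {
    Sp <- S; Sp[i, c_] <- Sp[i, c_] + eps
    Sm <- S; Sm[i, c_] <- Sm[i, c_] - eps
    expect_equal(gh3$g[i, c_], (loss(Sp) - loss(Sm)) / (2 * eps),
                 tolerance = 1e-5)
    Sp[i, c_] <- S[i, c_] + epsH
    Sm[i, c_] <- S[i, c_] - epsH
    expect_equal(gh3$h[i, c_],
                 (loss(Sp) - 2 * loss(S) + loss(Sm)) / epsH^2,
                 tolerance = 1e-5)
  }
  expect_error(softmaxGradHess(1L, matrix(c(Inf, 0), 1, 2)), "finite")
})

test_that("leaf weights minimize the per-leaf quadratic", {
  expect_equal(leafWeight(0, 5, 1), 0)
  expect_equal(leafWeight(2, 3, 1), -0.5)
  ## grid-search oracle for G*w + 1/2*(H+lambda)*w^2
  G <- 1.7; H <- 2.2; lambda <- 0.9
  grid <- seq(-2, 2, by = 1e-4)
  obj <- G * grid + 0.5 * (H + lambda) * grid^2
  expect_equal(leafWeight(G, H, lambda), grid[which.min(obj)],
               tolerance = 1e-3)
})

test_that("structure score follows the closed form", {
  ## single leaf with cancelling gradients: -1/2*0 + gamma
  expect_equal(structureScore(c(1, 1), c(1, -1), c(0.5, 0.5),
                              lambda = 0, gamma = 0.7), 0.7)
  ## two pure leaves vs one mixed leaf, by hand
  g <- c(-1, -1, 1, 1); h <- rep(1, 4)
  one <- structureScore(rep(1, 4), g, h, 1, 0)   # G=0 -> 0
  two <- structureScore(c(1, 1, 2, 2), g, h, 1, 0)
  expect_equal(one, 0)
  expect_equal(two, -0.5 * (4 / 3 + 4 / 3))
  ## gamma adds exactly gamma per leaf
  expect_equal(structureScore(c(1, 1, 2, 2), g, h, 1, 0.3) - two, 0.6)
})

test_that("bestSplit matches hand computation and exhaustive search", {
  ## perfectly separable 1-D two-group data, lambda = gamma = 0
  X <- matrix(c(1, 2, 3, 10, 11, 12), 6, 1)
  g <- c(-1, -1, -1, 1, 1, 1)
  h <- rep(1, 6)
  s <- bestSplit(X, g, h)
  expect_equal(s$feature, 1)
  expect_equal(s$threshold, 6.5)
  ## gain by hand: 1/2*(9/3 + 9/3 - 0) = 3
  expect_equal(s$gain, 3)
  ## gamma above the best raw gain: no split
  expect_null(bestSplit(X, g, h, gamma = 3.5))
  ## constant feature: no candidate
  expect_null(bestSplit(matrix(1, 6, 1), g, h))
  ## exhaustive oracle on random data
  set.seed(24)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    p <- sample(1:4, 1)
    X <- matrix(sample(seq(0, 1, 0.05), n * p, replace = TRUE), n, p)
    g <- rnorm(n); h <- runif(n, 0.1, 1)
    lambda <- runif(1, 0, 2); gamma <- runif(1, 0, 0.5)
    mcw <- runif(1, 0, 0.5)
    got <- bestSplit(X, g, h, lambda = lambda, gamma = gamma,
                     minChildWeight = mcw)
    want <- exhaustiveBestSplit(X, g, h, lambda, gamma, mcw)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
    }
  }
})

test_that("a depth-1 softmax stump equals the exhaustive optimal stump", {
  set.seed(25)
  X <- matrix(rnorm(24), 12, 2)
  y <- sample(2, 12, replace = TRUE)
  params <- boostParams(nRounds = 1, maxDepth = 1, eta = 1, lambda = 0,
                        gamma = 0, minChildWeight = 0, subsample = 1,
                        colsample = 1, seed = 1)
  fit <- boostFit(X, y, params)
  gh <- softmaxGradHess(y, matrix(0, 12, 2))
  for (cl in 1:2) {
    want <- exhaustiveBestSplit(X, gh$g[, cl], gh$h[, cl], 0, 0, 0)
    nodes <- fit@trees[[1]][[cl]]
    expect_equal(nodes[1, "feature"], want$feature, ignore_attr = TRUE)
    expect_equal(nodes[1, "threshold"], want$threshold, ignore_attr = TRUE)
  }
})

test_that("single squared-error tree yields shrunken residual means", {
  ## 6 points, one stump: leaf weight = -G/(H+lambda) = mean residual
  ## shrunk by n/(n+lambda), by hand
  X <- matrix(c(1, 2, 3, 10, 11, 12), 6, 1)
  y <- c(1, 1, 1, 5, 5, 5)
  params <- boostParams(nRounds = 1, maxDepth = 1, eta = 1, lambda = 2,
                        gamma = 0, minChildWeight = 0, subsample = 1,
                        colsample = 1, objective = "squarederror")
  fit <- boostFit(X, y, params)
  pred <- predictValue(fit, X)
  ## G = -sum(y) per leaf, H = 3 -> w = 3*mean/(3+2)
  expect_equal(pred[1:3], rep(3 * 1 / 5, 3))
  expect_equal(pred[4:6], rep(3 * 5 / 5, 3))
})

test_that("boosting separates a toy problem and is deterministic", {
  set.seed(26)
  X <- matrix(rnorm(80), 40, 2)
  y <- ifelse(X[, 1] + 0.3 * X[, 2] > 0, 1L, 2L)
  params <- boostParams(nRounds = 10, maxDepth = 3, subsample = 1,
                        colsample = 1, minChildWeight = 0, seed = 5)
  fit <- boostFit(X, y, params)
  expect_equal(mean(predictClass(fit, X) == y), 1.0)
  ## bitwise reproducibility (also with subsampling, same seed)
  params2 <- boostParams(nRounds = 5, subsample = 0.6, colsample = 0.5,
                         seed = 9)
  fitA <- boostFit(X, y, params2)
  fitB <- boostFit(X, y, params2)
  expect_identical(fitA@trees, fitB@trees)
  expect_error(boostFit(X, rep(1L, 40), params), "two classes")
})

test_that("the full-sample training objective is non-increasing", {
  set.seed(27)
  for (seed in 1:3) {
    X <- matrix(rnorm(60 * 3), 60, 3)
    y <- sample(3, 60, replace = TRUE)
    params <- boostParams(nRounds = 30, maxDepth = 3, subsample = 1,
                          colsample = 1, minChildWeight = 0, lambda = 1,
                          seed = seed)
    fit <- boostFit(X, y, params)
    expect_true(all(diff(fit@objectiveTrace) <= 1e-9))
  }
})

test_that("probabilities normalize and a zero-round ensemble is uniform", {
  set.seed(28)
  X <- matrix(rnorm(30), 10, 3)
  y <- sample(3, 10, replace = TRUE)
  fit0 <- boostFit(X, y, boostParams(nRounds = 0))
  p0 <- predictProba(fit0, X)
  expect_equal(p0, matrix(1 / 3, 10, 3), ignore_attr = TRUE)
  fit <- boostFit(X, y, boostParams(nRounds = 5, seed = 2))
  p <- predictProba(fit, X)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-12)
})

test_that("predictions agree with a reference boosting library", {
  skip_if_not_installed("xgboost")
  set.seed(29)
  x <- tinySpectra(3, 30, 20, seed = 31)
  X <- reflectance(x)
  y <- classLabels(x)
  params <- boostParams(nRounds = 40, maxDepth = 3, eta = 0.3, lambda = 1,
                        subsample = 1, colsample = 1, minChildWeight = 1,
                        seed = 1)
  fit <- boostFit(X, y, params)
  dtrain <- xgboost::xgb.DMatrix(X, label = y - 1)
  ref <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 3,
                  max_depth = 3, eta = 0.3, lambda = 1,
                  min_child_weight = 1, nthread = 1),
    data = dtrain, nrounds = 40, verbose = 0)
  pRef <- predict(ref, dtrain)
  if (is.null(dim(pRef))) pRef <- matrix(pRef, nrow(X), 3, byrow = TRUE)
  predRef <- max.col(pRef)
  agree <- mean(predictClass(fit, X) == predRef)
  expect_gte(agree, 0.95)
})

test_that("feature importance concentrates on informative features", {
  set.seed(30)
  X <- cbind(rnorm(100), rnorm(100), rnorm(100))
  y <- ifelse(X[, 2] > 0, 1L, 2L)
  fit <- boostFit(X, y, boostParams(nRounds = 10, subsample = 1,
                                    colsample = 1, minChildWeight = 0))
  imp <- featureImportance(fit)
  expect_equal(imp$feature[1], 2)
  expect_gt(imp$gain[1], sum(imp$gain) * 0.9)
})

test_that("persisted models restore with identical predictions", {
  set.seed(35)
  X <- matrix(rnorm(60), 30, 2)
  y <- ifelse(X[, 1] > 0, 1L, 3L)
  fit <- boostFit(X, y, boostParams(nRounds = 8, seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  saveEnsemble(fit, path)
  back <- readEnsemble(path)
  expect_identical(predictProba(back, X), predictProba(fit, X))
  expect_identical(back@params@eta, fit@params@eta)
  expect_error(readEnsemble({
    p2 <- withr::local_tempfile(); saveRDS(list(kind = "other"), p2); p2
  }), "not a BoostedEnsemble")
})
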