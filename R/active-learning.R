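## Pool-based active learning ("EAL" when wrapped around the boosted-tree
## learner): a small seed pool of labeled samples, a large unlabeled
## pool, and a held-out test split. Each iteration scores the pool with
## the current model, queries the most uncertain samples for their true
## labels (simulated annotator), refits, and evaluates on the test set.

#' Construct an active-learning protocol configuration
#'
#' Defaults reproduce the reference protocol on 750 samples: 30% test,
#' 52 initial labels, budget 60 in 5 iterations of 12, least-confidence
#' querying, 5 replicate runs.
#'
#' @param initialLabeled,budget,nIterations,batchSize,queryStrategy,testFraction,nRuns,seed
#'   see [ALConfig-class]; `batchSize` defaults to
#'   `budget / nIterations`, which must be integral.
#' @return an [ALConfig-class].
#' @export
alConfig <- function(initialLabeled = 52L, budget = 60L, nIterations = 5L,
                     batchSize = NULL, queryStrategy = "least_confidence",
                     testFraction = 0.3, nRuns = 5L, seed = 1L) {
  if (is.null(batchSize)) {
    if (budget > 0 && budget %% nIterations != 0)
      stop("budget must be divisible by nIterations")
    batchSize <- if (budget > 0) budget %/% nIterations else 0L
  }
  new("ALConfig", initialLabeled = as.integer(initialLabeled),
      budget = as.integer(budget), nIterations = as.integer(nIterations),
      batchSize = as.integer(batchSize), queryStrategy = queryStrategy,
      testFraction = testFraction, nRuns = as.integer(nRuns),
      seed = as.integer(seed))
}

#' Initialize labeled/unlabeled/test pools
#'
#' Draws a stratified test split of `testFraction`, then from the
#' remainder an initial labeled pool of `initialLabeled` samples with at
#' least one per class (one guaranteed per class, the rest uniform); the
#' rest form the unlabeled pool. Deterministic for a fixed seed.
#'
#' @param y integer class labels for the full dataset (codes `1..C`).
#' @param config an [alConfig()].
#' @return an [ALState-class] with empty history.
#' @export
initPools <- function(y, config) {
  y <- as.integer(y)
  n <- length(y)
  classes <- sort(unique(y))
  if (config@initialLabeled < length(classes))
    stop("initialLabeled (", config@initialLabeled,
         ") must be >= the number of classes (", length(classes), ")")
  withSeed(config@seed, {
    testIdx <- unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sampleFrom(idx, round(config@testFraction * length(idx)))
    }))
    trainIdx <- setdiff(seq_len(n), testIdx)
    if (config@initialLabeled >= length(trainIdx))
      stop("initialLabeled leaves no unlabeled pool")
    ## one guaranteed sample per class, remainder uniform
    seedIdx <- vapply(classes, function(cl) {
      idx <- intersect(trainIdx, which(y == cl))
      if (length(idx) == 0)
        stop("class ", cl, " has no samples outside the test split")
      if (length(idx) == 1) idx else sampleFrom(idx, 1)
    }, integer(1))
    rest <- setdiff(trainIdx, seedIdx)
    extra <- config@initialLabeled - length(seedIdx)
    labeled <- sort(c(seedIdx, if (extra > 0) sampleFrom(rest, extra)))
    new("ALState", labeledIdx = labeled,
        unlabeledIdx = sort(setdiff(trainIdx, labeled)),
        testIdx = sort(as.integer(testIdx)), history = list(),
        config = config)
  })
}

#' Least-confidence uncertainty scores
#'
#' `score_i = 1 - max_c p[i, c]`; higher means more uncertain.
#'
#' @param proba n x C probability matrix.
#' @return numeric scores.
#' @export
leastConfidence <- function(proba) 1 - apply(as.matrix(proba), 1, max)

#' Shannon-entropy uncertainty scores (nats)
#'
#' @param proba n x C probability matrix; `0 * log(0)` is taken as 0.
#' @return numeric scores.
#' @export
entropyScore <- function(proba) {
  proba <- as.matrix(proba)
  lp <- ifelse(proba > 0, log(proba), 0)
  -rowSums(proba * lp)
}

## size-safe sampling: never falls into sample()'s scalar-x surprise
sampleFrom <- function(x, size) x[sample.int(length(x), size)]

## ---- learner adapters -----------------------------------------------------
## A learner is a list(name, fit(X, y, seed) -> model,
## predictProba(model, X, nClasses) -> n x nClasses matrix). Probability
## columns always cover the full label set 1..nClasses even when a class
## is missing from the training labels.

expandProba <- function(p, seen, nClasses) {
  p <- as.matrix(p)
  out <- matrix(0, nrow(p), nClasses)
  out[, seen] <- p
  out
}

#' Learner adapters for the active-learning loop
#'
#' `learnerBoost` wraps the package's boosted-tree classifier (the "EAL"
#' configuration); `learnerLogistic` multinomial logistic regression
#' (the traditional AL baseline); `learnerRF` and `learnerDT` random
#' forest and a single decision tree (passive comparators).
#'
#' @param params a [boostParams()] for the boosted learner.
#' @return a learner: `list(name, fit(X, y, seed), predictProba(model,
#'   X, nClasses))`.
#' @export
learnerBoost <- function(params = boostParams()) {
  list(name = "EAL",
       fit = function(X, y, seed) {
         params@seed <- as.integer(seed)
         boostFit(X, y, params)
       },
       predictProba = function(model, X, nClasses) {
         expandProba(predictProba(model, X), model@classLevels, nClasses)
       })
}

#' @rdname learnerBoost
#' @export
learnerLogistic <- function() {
  list(name = "AL",
       fit = function(X, y, seed) {
         df <- data.frame(y = factor(y), X)
         utils::capture.output(
           m <- nnet::multinom(y ~ ., df, trace = FALSE,
                               MaxNWts = 100000, maxit = 200))
         m
       },
       predictProba = function(model, X, nClasses) {
         p <- predict(model, data.frame(X), type = "probs")
         lev <- as.integer(model$lev)
         if (is.null(dim(p))) {
           ## two-class multinom returns P(second level)
           p <- cbind(1 - p, p)
         }
         expandProba(p, lev, nClasses)
       })
}

#' @rdname learnerBoost
#' @export
learnerRF <- function() {
  list(name = "RF",
       fit = function(X, y, seed) {
         withSeed(seed, randomForest::randomForest(X, factor(y)))
       },
       predictProba = function(model, X, nClasses) {
         p <- predict(model, X, type = "prob")
         expandProba(p, as.integer(colnames(p)), nClasses)
       })
}

#' @rdname learnerBoost
#' @export
learnerDT <- function() {
  list(name = "DT",
       fit = function(X, y, seed) {
         df <- data.frame(y = factor(y), X)
         ## rpart defaults assume n >= 20; AL label budgets are smaller
         rpart::rpart(y ~ ., df, method = "class",
                      control = rpart::rpart.control(minsplit = 4,
                                                     xval = 0))
       },
       predictProba = function(model, X, nClasses) {
         p <- predict(model, data.frame(X), type = "prob")
         expandProba(p, as.integer(colnames(p)), nClasses)
       })
}

## ---- the loop -------------------------------------------------------------

queryScores <- function(proba, strategy, nPool) {
  switch(strategy,
         least_confidence = leastConfidence(proba),
         entropy = entropyScore(proba),
         random = runif(nPool),
         stop("unknown query strategy '", strategy, "'"))
}

#' Run the pool-based active-learning protocol
#'
#' Fits the learner on the seed pool, then per iteration: scores the
#' unlabeled pool with the current model, moves the `batchSize` most
#' uncertain samples (ties to the lowest index) with their true labels
#' into the labeled set, refits, and evaluates on the held-out test set.
#' After `nIterations` the labeled set has grown by exactly `budget`.
#' With `budget = 0` this degenerates to passive learning: one fit and
#' one evaluation.
#'
#' @param X feature matrix for the full dataset (any representation:
#'   raw, MS-preprocessed, or embedded spectra).
#' @param y integer class labels `1..C` for the full dataset (the
#'   simulated annotator's ground truth).
#' @param config an [alConfig()].
#' @param learner a learner adapter (default [learnerBoost()]).
#' @param state optional pre-built [ALState-class] (e.g. to share pools
#'   across methods); defaults to `initPools(y, config)`.
#' @param labelNoise probability that the simulated annotator returns a
#'   uniformly random wrong class for a queried sample (default 0:
#'   error-free annotation).
#' @return the completed [ALState-class]; each history entry holds
#'   `queried` (global indices), `scores` (their uncertainty), and
#'   `report` (test-set [MetricsReport-class]).
#' @export
runEAL <- function(X, y, config = alConfig(), learner = learnerBoost(),
                   state = NULL, labelNoise = 0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  yAnnotated <- y  # what the simulated annotator reports
  nClasses <- max(y)
  if (is.null(state)) state <- initPools(y, config)
  evalTest <- function(model) {
    p <- learner$predictProba(model, X[state@testIdx, , drop = FALSE],
                              nClasses)
    metricsReport(y[state@testIdx], max.col(p, ties.method = "first"),
                  nClasses)
  }
  model <- learner$fit(X[state@labeledIdx, , drop = FALSE],
                       y[state@labeledIdx], config@seed)
  if (config@budget == 0) {
    state@history <- list(list(queried = integer(0), scores = numeric(0),
                               report = evalTest(model)))
    return(state)
  }
  withSeed(config@seed + 500000L, {
    for (iter in seq_len(config@nIterations)) {
      if (length(state@unlabeledIdx) < config@batchSize)
        stop("unlabeled pool exhausted before the query budget was spent")
      proba <- learner$predictProba(
        model, X[state@unlabeledIdx, , drop = FALSE], nClasses)
      scores <- queryScores(proba, config@queryStrategy,
                            length(state@unlabeledIdx))
      pick <- order(-scores, state@unlabeledIdx)[seq_len(config@batchSize)]
      queried <- state@unlabeledIdx[pick]
      if (labelNoise > 0) {
        flip <- queried[runif(length(queried)) < labelNoise]
        for (i in flip)
          yAnnotated[i] <- sampleFrom(setdiff(seq_len(nClasses), y[i]), 1)
      }
      state@labeledIdx <- sort(c(state@labeledIdx, queried))
      state@unlabeledIdx <- setdiff(state@unlabeledIdx, queried)
      model <- learner$fit(X[state@labeledIdx, , drop = FALSE],
                           yAnnotated[state@labeledIdx], config@seed + iter)
      state@history[[iter]] <- list(queried = queried,
                                    scores = scores[pick],
                                    report = evalTest(model))
    }
  })
  validObject(state)
  state
}

#' Final test-set report of a completed run
#'
#' @param state a completed [ALState-class].
#' @return the last iteration's [MetricsReport-class].
#' @export
finalReport <- function(state) {
  state@history[[length(state@history)]]$report
}

#' Compare EAL with baseline methods under identical labeling budgets
#'
#' Per run: fresh pools from a per-run seed; active methods (EAL with
#' the boosted learner, AL with logistic regression) run the full query
#' protocol; passive methods (RF, DT) are fitted once on a random
#' labeled set of the same final size (`initialLabeled + budget`). All
#' methods share the pools and the test split within a run. Metrics are
#' averaged over `nRuns`.
#'
#' @inheritParams runEAL
#' @param activeLearners named list of learner adapters run actively.
#' @param passiveLearners named list run passively at matched label
#'   counts.
#' @return data.frame: one row per method with columns
#'   `oa`, `kappa`, `macro`, `recall`, `f1` (run averages).
#' @export
runComparison <- function(X, y, config = alConfig(),
                          activeLearners = list(EAL = learnerBoost(),
                                                AL = learnerLogistic()),
                          passiveLearners = list(RF = learnerRF(),
                                                 DT = learnerDT())) {
  y <- as.integer(y)
  nClasses <- max(y)
  methods <- c(names(activeLearners), names(passiveLearners))
  acc <- matrix(0, length(methods), 5,
                dimnames = list(methods,
                                c("oa", "kappa", "macro", "recall", "f1")))
  for (run in seq_len(config@nRuns)) {
    runCfg <- config
    runCfg@seed <- config@seed + (run - 1L) * 101L
    pools <- initPools(y, runCfg)
    reports <- list()
    for (nm in names(activeLearners)) {
      st <- runEAL(X, y, runCfg, activeLearners[[nm]], state = pools)
      reports[[nm]] <- finalReport(st)
    }
    ## passive: same final label count, drawn from the same train pool
    totalLabels <- runCfg@initialLabeled + runCfg@budget
    extra <- withSeed(runCfg@seed + 900000L,
                      sampleFrom(pools@unlabeledIdx,
                                 totalLabels - length(pools@labeledIdx)))
    labIdx <- sort(c(pools@labeledIdx, extra))
    for (nm in names(passiveLearners)) {
      lrn <- passiveLearners[[nm]]
      model <- lrn$fit(as.matrix(X)[labIdx, , drop = FALSE], y[labIdx],
                       runCfg@seed)
      p <- lrn$predictProba(model,
                            as.matrix(X)[pools@testIdx, , drop = FALSE],
                            nClasses)
      reports[[nm]] <- metricsReport(y[pools@testIdx],
                                     max.col(p, ties.method = "first"),
                                     nClasses)
    }
    for (nm in methods) {
      r <- reports[[nm]]
      acc[nm, ] <- acc[nm, ] + c(r@oa, r@kappa, r@macroPrecision,
                                 r@macroRecall, r@macroF1)
    }
  }
  as.data.frame(acc / config@nRuns)
}

setMethod("show", "ALState", function(object) {
  cat(sprintf(paste0("ALState: %d labeled | %d unlabeled | %d test",
                     " (%d iterations recorded)\n"),
              length(object@labeledIdx), length(object@unlabeledIdx),
              length(object@testIdx), length(object@history)))
})
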