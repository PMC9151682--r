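## End-to-end configuration and the reproducible benchmark grid. A single
## global seed deterministically derives every stage seed:
## generator = seed, sampling = seed + 1000, pools/AL = seed + 2000,
## learner fits = AL seed + iteration. Changing only the output directory
## changes no numeric result.

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with the shipped defaults:
#' the 15 x 50 x 125-band generator, MSC + window-5 uniform smoothing,
#' Isomap with k = 10 and automatic dimension choice over 1-20, the
#' tuned boosting parameters, and the 52/60/5 active-learning protocol.
#'
#' @param seed global seed.
#' @return a named nested list (see `str(pipelineConfig())`).
#' @export
pipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(nClasses = 15L, nPerClass = 50L, nBands = 125L,
                     wavelengthRange = c(400, 1000),
                     additiveOffsetSd = 0.01,
                     multiplicativeSlopeRange = c(0.85, 1.15),
                     noiseSd = 0.005),
    preprocess = list(halfWidth = 2L, kind = "uniform"),
    manifold = list(k = 10L, zRange = c(1L, 20L), Z = "auto"),
    boosting = list(nRounds = 160L, maxDepth = 5L, eta = 0.1, lambda = 1,
                    gamma = 0, minChildWeight = 1, subsample = 0.6,
                    colsample = 0.6),
    activeLearning = list(initialLabeled = 52L, budget = 60L,
                          nIterations = 5L,
                          queryStrategy = "least_confidence",
                          testFraction = 0.3, nRuns = 5L))
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys at any level are rejected; missing keys fall back to the
#' defaults of [pipelineConfig()].
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- pipelineConfig()
  merge1 <- function(d, u, where) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown configuration key", if (length(unknown) > 1) "s",
           " in ", where, ": ", paste(unknown, collapse = ", "))
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]]))
        merge1(d[[k]], u[[k]], paste0(where, "$", k)) else u[[k]]
    }
    d
  }
  validatePipelineConfig(merge1(def, user, "config"))
}

#' @rdname readPipelineConfig
#' @param config a configuration list to validate.
#' @export
validatePipelineConfig <- function(config) {
  s <- config$synthetic
  if (s$nClasses < 2 || s$nPerClass < 1 || s$nBands < 8)
    stop("synthetic: nClasses >= 2, nPerClass >= 1, nBands >= 8 required")
  if (config$preprocess$halfWidth < 0)
    stop("preprocess: halfWidth must be >= 0")
  if (config$manifold$k < 1) stop("manifold: k must be >= 1")
  al <- config$activeLearning
  if (al$budget %% al$nIterations != 0)
    stop("activeLearning: budget must be divisible by nIterations")
  config
}

configBoostParams <- function(config, seed) {
  b <- config$boosting
  boostParams(nRounds = b$nRounds, maxDepth = b$maxDepth, eta = b$eta,
              lambda = b$lambda, gamma = b$gamma,
              minChildWeight = b$minChildWeight, subsample = b$subsample,
              colsample = b$colsample, seed = seed)
}

configALConfig <- function(config, seed) {
  al <- config$activeLearning
  alConfig(initialLabeled = al$initialLabeled, budget = al$budget,
           nIterations = al$nIterations,
           queryStrategy = al$queryStrategy,
           testFraction = al$testFraction, nRuns = al$nRuns, seed = seed)
}

#' Simulate the configured dataset
#'
#' @param config a [pipelineConfig()].
#' @param outdir optional directory; when given, the dataset is written
#'   as `spectra.csv` together with the resolved `config.yaml`.
#' @return a [SpectraSet-class].
#' @export
cmdSimulate <- function(config = pipelineConfig(), outdir = NULL) {
  s <- config$synthetic
  profiles <- makeClassProfiles(s$nClasses, s$nBands, s$wavelengthRange,
                                seed = config$seed)
  sc <- scatterModel(s$additiveOffsetSd, s$multiplicativeSlopeRange,
                     s$noiseSd)
  x <- simulateSpectra(profiles, s$nPerClass, sc,
                       seed = config$seed + 1000L)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeSpectraCSV(x, file.path(outdir, "spectra.csv"))
    yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  }
  x
}

#' Preprocess spectra with the configured MS stage
#'
#' @param x a [SpectraSet-class].
#' @inheritParams cmdSimulate
#' @return as [msTransform()]: list of `spectra` and `transform`.
#' @export
cmdPreprocess <- function(x, config = pipelineConfig(), outdir = NULL) {
  sm <- smoothSpec(config$preprocess$halfWidth, config$preprocess$kind)
  res <- msTransform(x, sm)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeSpectraCSV(res$spectra, file.path(outdir, "spectra_ms.csv"))
  }
  res
}

#' Embed spectra with the configured Isomap stage
#'
#' With `Z = "auto"` the dimensionality is chosen by reconstruction RMSE
#' over the configured range; otherwise the configured fixed `Z` is used.
#'
#' @param x a [SpectraSet-class] or feature matrix.
#' @inheritParams cmdSimulate
#' @return list with `model` ([IsomapModel-class]), `Y`, `Z` and (in auto
#'   mode) `rmse` (the selection curve).
#' @export
cmdEmbed <- function(x, config = pipelineConfig(), outdir = NULL) {
  X <- if (is(x, "SpectraSet")) reflectance(x) else as.matrix(x)
  m <- config$manifold
  if (identical(m$Z, "auto")) {
    zr <- seq(m$zRange[1], min(m$zRange[2], nrow(X) - 1L))
    sel <- selectComponents(X, m$k, zr, onDisconnect = "bridge")
    out <- list(model = sel$model, Y = embedding(sel$model, sel$Z),
                Z = sel$Z, rmse = sel$rmse)
  } else {
    model <- isomapFit(X, m$k, as.integer(m$Z), onDisconnect = "bridge")
    out <- list(model = model, Y = model@Y, Z = model@Z, rmse = NULL)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(out$Y), file.path(outdir, "embedding.csv"),
                     row.names = FALSE)
    if (!is.null(out$rmse))
      utils::write.csv(data.frame(Z = as.integer(names(out$rmse)),
                                  rmse = out$rmse),
                       file.path(outdir, "rmse_curve.csv"), row.names = FALSE)
  }
  out
}

## fit preprocessing/embedding on the train partition only, transform the
## test split against it, and return the full-feature matrix for the run
pipelineFeatures <- function(x, config, pools,
                             preprocessing = c("ms", "msc", "nirmaf", "raw"),
                             embed = TRUE) {
  preprocessing <- match.arg(preprocessing)
  R <- reflectance(x)
  trainIdx <- sort(c(pools@labeledIdx, pools@unlabeledIdx))
  testIdx <- pools@testIdx
  sm <- smoothSpec(config$preprocess$halfWidth, config$preprocess$kind)
  Rtr <- R[trainIdx, , drop = FALSE]
  Rte <- R[testIdx, , drop = FALSE]
  feats <- switch(preprocessing,
    raw = list(train = Rtr, test = Rte),
    msc = {
      model <- mscFit(Rtr, "mean")
      list(train = mscApply(model, Rtr), test = mscApply(model, Rte))
    },
    nirmaf = list(train = movingWindowSmooth(Rtr, sm),
                  test = movingWindowSmooth(Rte, sm)),
    ms = {
      model <- mscFit(Rtr, "mean")
      list(train = movingWindowSmooth(mscApply(model, Rtr), sm),
           test = movingWindowSmooth(mscApply(model, Rte), sm))
    })
  if (embed) {
    m <- config$manifold
    if (identical(m$Z, "auto")) {
      zr <- seq(m$zRange[1], min(m$zRange[2], nrow(feats$train) - 1L))
      sel <- selectComponents(feats$train, m$k, zr, onDisconnect = "bridge")
      model <- sel$model
      Ytr <- embedding(model, sel$Z)
      Yte <- isomapTransform(model, feats$test, sel$Z)
    } else {
      model <- isomapFit(feats$train, m$k, as.integer(m$Z),
                         onDisconnect = "bridge")
      Ytr <- model@Y
      Yte <- isomapTransform(model, feats$test)
    }
    feats <- list(train = Ytr, test = Yte)
  }
  X <- matrix(NA_real_, nrow(R), ncol(feats$train))
  X[trainIdx, ] <- feats$train
  X[testIdx, ] <- feats$test
  X
}

#' Run one configured classification pipeline
#'
#' Builds pools, fits the chosen preprocessing (and optionally Isomap)
#' on the train partition only, and runs the active-learning protocol in
#' that feature space.
#'
#' @param x a labeled [SpectraSet-class].
#' @param config a [pipelineConfig()].
#' @param preprocessing `"ms"`, `"msc"`, `"nirmaf"` or `"raw"`.
#' @param embed apply the Isomap stage after preprocessing?
#' @param queryStrategy override the configured query strategy.
#' @param seed seed for pools and the AL loop (defaults to
#'   `config$seed + 2000`).
#' @return the completed [ALState-class].
#' @export
runPipeline <- function(x, config = pipelineConfig(), preprocessing = "ms",
                        embed = TRUE, queryStrategy = NULL, seed = NULL) {
  y <- classLabels(x)
  if (anyNA(y)) stop("the pipeline needs fully labeled data")
  if (is.null(seed)) seed <- config$seed + 2000L
  cfg <- configALConfig(config, seed)
  if (!is.null(queryStrategy)) cfg@queryStrategy <- queryStrategy
  pools <- initPools(y, cfg)
  X <- pipelineFeatures(x, config, pools, preprocessing, embed)
  runEAL(X, y, cfg, learnerBoost(configBoostParams(config, seed)),
         state = pools)
}

#' The full benchmark grid
#'
#' Reproduces the experiment shape of the reference study on the
#' synthetic benchmark: a preprocessing grid (MSC, Nirmaf smoothing and
#' the fused MS stage, each with and without the Isomap embedding, all
#' under the EAL protocol) and a learner comparison (active EAL and
#' logistic-regression AL versus passive RF and DT at matched label
#' counts).
#'
#' @param config a [pipelineConfig()].
#' @param outdir optional run directory for the result CSVs and the
#'   resolved config.
#' @return list with data.frames `preprocessing` (6 rows: method, oa,
#'   kappa) and `learners` (4 rows: oa, kappa, macro, recall, f1).
#' @export
runBenchmark <- function(config = pipelineConfig(), outdir = NULL) {
  x <- cmdSimulate(config)
  y <- classLabels(x)
  grid <- expand.grid(prep = c("msc", "nirmaf", "ms"),
                      embed = c(FALSE, TRUE), stringsAsFactors = FALSE)
  prepRows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- runPipeline(x, config, grid$prep[i], grid$embed[i])
    r <- finalReport(st)
    name <- paste0(toupper(grid$prep[i]),
                   if (grid$embed[i]) "-Isomap-EAL" else "-FS-EAL")
    if (grid$prep[i] == "ms" && grid$embed[i]) name <- "MSM-EAL"
    data.frame(method = name, oa = r@oa, kappa = r@kappa)
  })
  preprocessing <- do.call(rbind, prepRows)
  ## learner table in the MSM feature space
  cfg <- configALConfig(config, config$seed + 2000L)
  pools <- initPools(y, cfg)
  X <- pipelineFeatures(x, config, pools, "ms", embed = TRUE)
  learners <- runComparison(
    X, y, cfg,
    activeLearners = list(EAL = learnerBoost(configBoostParams(
      config, config$seed + 2000L)), AL = learnerLogistic()))
  learners <- cbind(method = rownames(learners), learners)
  rownames(learners) <- NULL
  out <- list(preprocessing = preprocessing, learners = learners)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(preprocessing,
                     file.path(outdir, "preprocessing_grid.csv"),
                     row.names = FALSE)
    utils::write.csv(learners, file.path(outdir, "learner_comparison.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  }
  out
}
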