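## Single-file persistence for fitted models. Format: R native
## serialization (version 3) of a named list -- a `kind` tag, a format
## `version`, and the object's arrays/parameters -- so archives remain
## readable even if the S4 class definitions evolve.

archiveVersion <- 1L

#' Persist and restore fitted models
#'
#' `saveIsomapModel()`/`readIsomapModel()` and
#' `saveEnsemble()`/`readEnsemble()` write a fitted model to a single
#' archive file and rebuild it. Reading validates the archive kind and
#' version and reconstructs a model whose `isomapTransform()` /
#' `predictProba()` output is identical to the original's.
#'
#' @param model a fitted [IsomapModel-class].
#' @param path archive file path.
#' @return the save functions return `invisible(path)`; the read
#'   functions return the restored model.
#' @export
saveIsomapModel <- function(model, path) {
  stopifnot(is(model, "IsomapModel"))
  payload <- list(kind = "IsomapModel", version = archiveVersion,
                  X = model@X, DG = model@DG, evals = model@evals,
                  evecs = model@evecs, Y = model@Y, k = model@k,
                  Z = model@Z, nClipped = model@nClipped,
                  graphN = model@graph@n, graphK = model@graph@k,
                  graphEdges = model@graph@edges)
  saveRDS(payload, path, version = 3)
  invisible(path)
}

checkArchive <- function(payload, kind, path) {
  if (!is.list(payload) || !identical(payload$kind, kind))
    stop("'", path, "' is not a ", kind, " archive")
  if (payload$version > archiveVersion)
    stop("archive version ", payload$version, " is newer than this package")
  payload
}

#' @rdname saveIsomapModel
#' @export
readIsomapModel <- function(path) {
  p <- checkArchive(readRDS(path), "IsomapModel", path)
  graph <- new("NeighborGraph", n = p$graphN, k = p$graphK,
               edges = p$graphEdges)
  new("IsomapModel", X = p$X, graph = graph, DG = p$DG, evals = p$evals,
      evecs = p$evecs, Y = p$Y, k = p$k, Z = p$Z, nClipped = p$nClipped)
}

#' @rdname saveIsomapModel
#' @param ensemble a fitted [BoostedEnsemble-class].
#' @export
saveEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "BoostedEnsemble"))
  pr <- ensemble@params
  payload <- list(kind = "BoostedEnsemble", version = archiveVersion,
                  trees = ensemble@trees, baseScore = ensemble@baseScore,
                  classLevels = ensemble@classLevels,
                  nFeatures = ensemble@nFeatures,
                  objectiveTrace = ensemble@objectiveTrace,
                  params = list(nRounds = pr@nRounds, maxDepth = pr@maxDepth,
                                eta = pr@eta, lambda = pr@lambda,
                                gamma = pr@gamma,
                                minChildWeight = pr@minChildWeight,
                                subsample = pr@subsample,
                                colsample = pr@colsample,
                                nClasses = pr@nClasses,
                                objective = pr@objective, seed = pr@seed))
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname saveIsomapModel
#' @export
readEnsemble <- function(path) {
  p <- checkArchive(readRDS(path), "BoostedEnsemble", path)
  new("BoostedEnsemble", trees = p$trees,
      params = do.call(boostParams, p$params),
      baseScore = p$baseScore, classLevels = p$classLevels,
      nFeatures = p$nFeatures, objectiveTrace = p$objectiveTrace)
}
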