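## Central S4 classes. Containers only -- constructors and methods live in
## the per-stage files.

#' SpectraSet: labeled reflectance spectra
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' `reflectance`, with bands as rows and samples as columns. Wavelengths
#' (nm, strictly increasing) live in `rowData(x)$wavelength`; integer
#' class labels (or `NA` when unlabeled) in `colData(x)$label`. Use the
#' accessors [reflectance()], [wavelengths()], [classLabels()] and
#' [sampleIds()] rather than slots; `reflectance()` returns the
#' conventional samples x bands orientation.
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- NULL
  if (!"reflectance" %in% assayNames(object))
    msg <- c(msg, "assay 'reflectance' is missing")
  if (!"wavelength" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'wavelength' is missing")
  else {
    w <- rowData(object)$wavelength
    if (anyNA(w) || any(diff(w) <= 0))
      msg <- c(msg, "wavelengths must be finite and strictly increasing")
  }
  if ("reflectance" %in% assayNames(object) &&
      !all(is.finite(assay(object, "reflectance"))))
    msg <- c(msg, "reflectance values must all be finite")
  if (!"label" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'label' is missing")
  if (is.null(msg)) TRUE else msg
})

#' HyperCube: a minimal ENVI-style hyperspectral image cube
#'
#' Raw image cube with dimensions lines x samples x bands plus the parsed
#' header fields (`samples`, `lines`, `bands`, `data type`, `interleave`,
#' `byte order`, optional `wavelength`). Only the BIL interleave is
#' supported; see [readENVI()].
#'
#' @slot cube three-dimensional numeric array, `[line, sample, band]`.
#' @slot header named list of header fields.
#' @export
setClass("HyperCube", representation(cube = "array", header = "list"))

setValidity("HyperCube", function(object) {
  d <- dim(object@cube)
  h <- object@header
  if (length(d) != 3L)
    return("cube must be a 3-d array [line, sample, band]")
  need <- c("lines", "samples", "bands")
  if (!all(need %in% names(h)))
    return("header must contain lines, samples and bands")
  if (!identical(as.integer(d),
                 as.integer(c(h$lines, h$samples, h$bands))))
    return("cube dimensions do not match header counts")
  if (!is.null(h$interleave) && !identical(tolower(h$interleave), "bil"))
    return("only interleave 'bil' is supported")
  TRUE
})

#' MSCModel: fitted multiplicative scatter correction
#'
#' Per-sample ordinary-least-squares fit of each spectrum against a
#' reference spectrum (by default the per-band mean of the fitting set).
#' Correction is `(x - offset) / slope`.
#'
#' @slot reference reference spectrum (length = band count).
#' @slot offset per-sample additive baseline estimates.
#' @slot slope per-sample multiplicative slope estimates (nonzero).
#' @export
setClass("MSCModel",
         representation(reference = "numeric", offset = "numeric",
                        slope = "numeric"))

#' SmoothSpec: a weighted moving-window smoothing kernel
#'
#' @slot n half width in bands; the window spans `2n + 1` bands.
#' @slot weights nonnegative weights of length `2n + 1`, normalized to
#'   sum to one.
#' @slot kind `"uniform"` or `"triangular"`.
#' @export
setClass("SmoothSpec",
         representation(n = "integer", weights = "numeric", kind = "character"))

setValidity("SmoothSpec", function(object) {
  if (length(object@weights) != 2L * object@n + 1L)
    return("weights must have length 2n + 1")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("weights must sum to 1")
  TRUE
})

#' MSTransform: the fitted MS preprocessing stage (MSC + smoothing)
#'
#' Captures the training-set MSC reference so held-out spectra are always
#' corrected against the training mean, never their own.
#'
#' @slot msc fitted [MSCModel-class].
#' @slot smooth the [SmoothSpec-class] used.
#' @export
setClass("MSTransform",
         representation(msc = "MSCModel", smooth = "SmoothSpec"))

#' NeighborGraph: symmetrized k-nearest-neighbor graph
#'
#' @slot n number of nodes.
#' @slot k neighbors per node before symmetrization.
#' @slot edges three-column matrix `(i, j, weight)` with `i < j`;
#'   weights are Euclidean distances (floored at 1e-12).
#' @export
setClass("NeighborGraph",
         representation(n = "integer", k = "integer", edges = "matrix"))

#' IsomapModel: fitted Isomap embedding
#'
#' Stores the training points, the k-NN graph, the geodesic distance
#' matrix, the full eigendecomposition of the double-centered squared
#' distance matrix, and the Z-dimensional embedding `Y = V_Z F_Z^{1/2}`.
#'
#' @slot X training points (n x p, preprocessed spectral space).
#' @slot graph the [NeighborGraph-class].
#' @slot DG n x n geodesic distance matrix.
#' @slot evals eigenvalues, descending.
#' @slot evecs unit-norm eigenvectors (columns), sign-fixed.
#' @slot Y n x Z embedding.
#' @slot k,Z the parameters used.
#' @slot nClipped number of negative eigenvalues clipped to zero among
#'   the first Z.
#' @export
setClass("IsomapModel",
         representation(X = "matrix", graph = "NeighborGraph", DG = "matrix",
                        evals = "numeric", evecs = "matrix", Y = "matrix",
                        k = "integer", Z = "integer", nClipped = "integer"))

#' BoostParams: hyperparameters of the boosted-tree learner
#'
#' Defaults are the shipped reference configuration: 160 rounds,
#' depth 5, eta 0.1, lambda 1, min_child_weight 1, subsample 0.6,
#' colsample 0.6.
#'
#' @slot nRounds boosting rounds.
#' @slot maxDepth maximum tree depth.
#' @slot eta learning rate in (0, 1].
#' @slot lambda L2 penalty on leaf weights (>= 0).
#' @slot gamma per-leaf split penalty (>= 0).
#' @slot minChildWeight minimum Hessian sum per child.
#' @slot subsample row fraction per tree in (0, 1].
#' @slot colsample feature fraction per tree in (0, 1].
#' @slot nClasses number of classes (>= 2), or 0 to infer from data.
#' @slot objective `"softmax"` or `"squarederror"`.
#' @slot seed integer seed driving row/column subsampling.
#' @export
setClass("BoostParams",
         representation(nRounds = "integer", maxDepth = "integer",
                        eta = "numeric", lambda = "numeric", gamma = "numeric",
                        minChildWeight = "numeric", subsample = "numeric",
                        colsample = "numeric", nClasses = "integer",
                        objective = "character", seed = "integer"))

setValidity("BoostParams", function(object) {
  msg <- NULL
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (object@eta <= 0 || object@eta > 1) msg <- c(msg, "eta must be in (0, 1]")
  if (object@subsample <= 0 || object@subsample > 1)
    msg <- c(msg, "subsample must be in (0, 1]")
  if (object@colsample <= 0 || object@colsample > 1)
    msg <- c(msg, "colsample must be in (0, 1]")
  if (!object@objective %in% c("softmax", "squarederror"))
    msg <- c(msg, "objective must be 'softmax' or 'squarederror'")
  if (is.null(msg)) TRUE else msg
})

#' BoostedEnsemble: a fitted second-order gradient-boosted tree model
#'
#' @slot trees list of rounds; each round a list of per-class node
#'   matrices (columns: feature, threshold, left, right, weight, gain,
#'   cover).
#' @slot params the [BoostParams-class] used.
#' @slot baseScore raw score added to every class before the trees.
#' @slot classLevels the original class codes, in model column order.
#' @slot nFeatures number of features seen at fit time.
#' @slot objectiveTrace per-round regularized training objective
#'   (training loss plus the penalties of that round's trees).
#' @export
setClass("BoostedEnsemble",
         representation(trees = "list", params = "BoostParams",
                        baseScore = "numeric", classLevels = "integer",
                        nFeatures = "integer", objectiveTrace = "numeric"))

#' ALConfig: pool-based active-learning protocol settings
#'
#' Defaults mirror the reference protocol: 30% held-out test split, 52
#' initial labels (at least one per class), a budget of 60 queries spent
#' in 5 iterations of 12, least-confidence querying, 5 replicate runs.
#'
#' @slot initialLabeled size of the seed labeled pool.
#' @slot budget total number of label queries.
#' @slot nIterations number of query iterations.
#' @slot batchSize queries per iteration (`budget / nIterations`).
#' @slot queryStrategy one of `"least_confidence"`, `"entropy"`,
#'   `"random"`.
#' @slot testFraction held-out test fraction in (0, 1).
#' @slot nRuns replicate runs for averaged comparisons.
#' @slot seed integer seed.
#' @export
setClass("ALConfig",
         representation(initialLabeled = "integer", budget = "integer",
                        nIterations = "integer", batchSize = "integer",
                        queryStrategy = "character", testFraction = "numeric",
                        nRuns = "integer", seed = "integer"))

setValidity("ALConfig", function(object) {
  msg <- NULL
  if (object@budget > 0 &&
      object@batchSize * object@nIterations != object@budget)
    msg <- c(msg, "batchSize * nIterations must equal budget")
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must be in (0, 1)")
  if (!object@queryStrategy %in% c("least_confidence", "entropy", "random"))
    msg <- c(msg, "unknown queryStrategy")
  if (is.null(msg)) TRUE else msg
})

#' ALState: the evolving labeled/unlabeled/test partition
#'
#' @slot labeledIdx,unlabeledIdx,testIdx disjoint 1-based sample indices
#'   partitioning the dataset.
#' @slot history per-iteration records: queried indices, their
#'   uncertainty scores, and the test-set [MetricsReport-class].
#' @slot config the [ALConfig-class] in force.
#' @export
setClass("ALState",
         representation(labeledIdx = "integer", unlabeledIdx = "integer",
                        testIdx = "integer", history = "list",
                        config = "ALConfig"))

setValidity("ALState", function(object) {
  all3 <- c(object@labeledIdx, object@unlabeledIdx, object@testIdx)
  if (anyDuplicated(all3))
    return("labeled, unlabeled and test indices must be disjoint")
  TRUE
})

#' MetricsReport: confusion matrix and derived multiclass scores
#'
#' @slot confusion C x C count matrix, rows = true class, columns =
#'   predicted class.
#' @slot oa overall accuracy in `[0, 1]`.
#' @slot kappa Cohen's kappa (chance-corrected agreement).
#' @slot macroPrecision,macroRecall,macroF1 unweighted class means.
#' @export
setClass("MetricsReport",
         representation(confusion = "matrix", oa = "numeric",
                        kappa = "numeric", macroPrecision = "numeric",
                        macroRecall = "numeric", macroF1 = "numeric"))
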