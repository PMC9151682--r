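## Second-order gradient-boosted regression trees with softmax multiclass
## output. The regularized objective is
##   L = sum_i l(y_i, yhat_i) + sum_k [ gamma*T_k + 1/2 lambda ||w_k||^2 ],
## expanded to second order in the new tree's outputs; per leaf the
## optimum is w* = -G/(H + lambda) with structure score
##   -1/2 sum_leaves G^2/(H + lambda) + gamma*T.
## Multiclass is handled one tree per class per round with a shared
## softmax; the exact greedy split search lives in src/boosting.cpp.

#' Construct boosted-tree hyperparameters
#'
#' Defaults are the tuned reference configuration (160 rounds, depth 5,
#' eta 0.1, lambda 1, min child weight 1, row/column subsampling 0.6).
#'
#' @param nRounds,maxDepth,eta,lambda,gamma,minChildWeight,subsample,colsample,seed
#'   see [BoostParams-class].
#' @param nClasses number of classes, or 0 to infer from the training
#'   labels.
#' @param objective `"softmax"` (multiclass cross-entropy) or
#'   `"squarederror"` (single-output regression).
#' @return a [BoostParams-class].
#' @export
boostParams <- function(nRounds = 160L, maxDepth = 5L, eta = 0.1,
                        lambda = 1, gamma = 0, minChildWeight = 1,
                        subsample = 0.6, colsample = 0.6, nClasses = 0L,
                        objective = "softmax", seed = 27L) {
  new("BoostParams", nRounds = as.integer(nRounds),
      maxDepth = as.integer(maxDepth), eta = eta, lambda = lambda,
      gamma = gamma, minChildWeight = minChildWeight, subsample = subsample,
      colsample = colsample, nClasses = as.integer(nClasses),
      objective = objective, seed = as.integer(seed))
}

#' Softmax cross-entropy gradients and Hessians
#'
#' For `p = softmax(rawScores)` per row: `g[i, c] = p[i, c] - 1(y_i = c)`
#' and `h[i, c] = p[i, c] (1 - p[i, c])` (the diagonal second
#' derivative).
#'
#' @param labels integer class labels in `1..nClasses`.
#' @param rawScores n x nClasses matrix of raw (pre-softmax) scores.
#' @return list with matrices `g` and `h`.
#' @export
softmaxGradHess <- function(labels, rawScores) {
  rawScores <- as.matrix(rawScores)
  if (!all(is.finite(rawScores))) stop("raw scores must be finite")
  n <- nrow(rawScores)
  C <- ncol(rawScores)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > C))
    stop("labels must lie in 1..", C)
  p <- exp(rawScores - apply(rawScores, 1, max))
  p <- p / rowSums(p)
  g <- p
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  list(g = g, h = p * (1 - p))
}

#' Optimal leaf weight under the second-order objective
#'
#' @param G,H sums of gradients and Hessians over the leaf.
#' @param lambda L2 penalty.
#' @return `-G / (H + lambda)`.
#' @export
leafWeight <- function(G, H, lambda) -G / (H + lambda)

#' Structure score of a fixed tree partition
#'
#' `-1/2 * sum_leaves (sum g)^2 / (sum h + lambda) + gamma * T`; lower is
#' better.
#'
#' @param partition integer leaf assignment per sample (any codes).
#' @param g,h per-sample gradients and Hessians.
#' @param lambda,gamma regularization parameters.
#' @return scalar score.
#' @export
structureScore <- function(partition, g, h, lambda, gamma) {
  Gs <- tapply(g, partition, sum)
  Hs <- tapply(h, partition, sum)
  -0.5 * sum(Gs^2 / (Hs + lambda)) + gamma * length(Gs)
}

#' Exact greedy best split for one node
#'
#' Scans every candidate feature's sorted unique values; the gain of a
#' split is the decrease in structure score,
#' `1/2 [GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda)] - gamma`.
#' A split is returned only if its gain is positive and both children
#' meet `minChildWeight`; ties prefer the lower feature index, then the
#' lower threshold.
#'
#' @param X feature matrix.
#' @param g,h per-sample gradients and Hessians (same length as rows
#'   considered).
#' @param rows,cols 1-based row/column indices defining the node and the
#'   candidate features (defaults: all).
#' @param lambda,gamma,minChildWeight regularization parameters.
#' @return list `(feature, threshold, gain)` or `NULL` when no
#'   admissible split exists. Samples go left when `x < threshold`.
#' @export
bestSplit <- function(X, g, h, rows = seq_len(nrow(X)),
                      cols = seq_len(ncol(X)), lambda = 0, gamma = 0,
                      minChildWeight = 0) {
  s <- cpp_best_split(as.matrix(X), as.numeric(g), as.numeric(h),
                      as.integer(rows), as.integer(cols),
                      lambda, gamma, minChildWeight)
  if (s$feature == 0) NULL else s
}

## regularization penalty of one fitted tree
treePenalty <- function(nodes, lambda, gamma) {
  leaves <- nodes[, "feature"] == 0
  gamma * sum(leaves) + 0.5 * lambda * sum(nodes[leaves, "weight"]^2)
}

#' Fit a gradient-boosted tree ensemble
#'
#' @param X numeric feature matrix (finite values).
#' @param y integer class labels (any integer codes; >= 2 distinct) for
#'   the softmax objective, or a numeric response for
#'   `objective = "squarederror"`.
#' @param params a [boostParams()].
#' @return a [BoostedEnsemble-class]. `objectiveTrace` records, per
#'   round, the training loss plus the regularization penalties of that
#'   round's trees (the per-round objective); in full-sample mode it is
#'   non-increasing.
#' @examples
#' X <- matrix(rnorm(60), 30, 2)
#' y <- ifelse(X[, 1] > 0, 1L, 2L)
#' fit <- boostFit(X, y, boostParams(nRounds = 10, subsample = 1,
#'                                   colsample = 1))
#' mean(predictClass(fit, X) == y)
#' @export
boostFit <- function(X, y, params = boostParams()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X)
  p <- ncol(X)
  squared <- params@objective == "squarederror"
  if (squared) {
    levels <- 1L
    C <- 1L
    yIdx <- as.numeric(y)
  } else {
    levels <- sort(unique(as.integer(y)))
    C <- length(levels)
    if (C < 2) stop("y must contain at least two classes")
    if (params@nClasses > 0 && params@nClasses != C)
      stop("params nClasses (", params@nClasses,
           ") does not match the data (", C, ")")
    yIdx <- match(as.integer(y), levels)
  }
  scores <- matrix(0, n, C)
  trees <- vector("list", params@nRounds)
  trace <- numeric(params@nRounds)
  nRow <- max(1L, as.integer(floor(params@subsample * n)))
  nCol <- max(1L, as.integer(floor(params@colsample * p)))
  withSeed(params@seed, {
    for (t in seq_len(params@nRounds)) {
      if (squared) {
        g <- scores[, 1] - yIdx
        h <- rep(1, n)
        gh <- list(g = cbind(g), h = cbind(h))
      } else {
        gh <- softmaxGradHess(yIdx, scores)
      }
      round_ <- vector("list", C)
      penalty <- 0
      for (cl in seq_len(C)) {
        rows <- if (nRow < n) sort(sample.int(n, nRow)) else seq_len(n)
        cols <- if (nCol < p) sort(sample.int(p, nCol)) else seq_len(p)
        nodes <- cpp_build_tree(X, gh$g[, cl], gh$h[, cl],
                                rows, cols, params@maxDepth, params@lambda,
                                params@gamma, params@minChildWeight)
        round_[[cl]] <- nodes
        scores[, cl] <- scores[, cl] +
          params@eta * cpp_predict_tree(nodes, X)
        penalty <- penalty + treePenalty(nodes, params@lambda, params@gamma)
      }
      trees[[t]] <- round_
      loss <- if (squared) {
        0.5 * sum((scores[, 1] - yIdx)^2)
      } else {
        pmax_ <- apply(scores, 1, max)
        lse <- pmax_ + log(rowSums(exp(scores - pmax_)))
        sum(lse - scores[cbind(seq_len(n), yIdx)])
      }
      trace[t] <- loss + penalty
    }
  })
  new("BoostedEnsemble", trees = trees, params = params, baseScore = 0,
      classLevels = if (squared) integer(0) else levels,
      nFeatures = p, objectiveTrace = trace)
}

rawScores <- function(ensemble, X) {
  X <- as.matrix(X)
  if (ncol(X) != ensemble@nFeatures)
    stop("X has ", ncol(X), " features, ensemble expects ",
         ensemble@nFeatures)
  C <- max(1L, length(ensemble@classLevels))
  scores <- matrix(ensemble@baseScore, nrow(X), C)
  for (round_ in ensemble@trees)
    for (cl in seq_len(C))
      scores[, cl] <- scores[, cl] +
        ensemble@params@eta * cpp_predict_tree(round_[[cl]], X)
  scores
}

#' Class probabilities from a boosted ensemble
#'
#' Softmax of the accumulated raw scores; rows sum to one. A zero-round
#' ensemble returns uniform rows.
#'
#' @param ensemble a [BoostedEnsemble-class].
#' @param X feature matrix.
#' @return n x nClasses probability matrix, columns named by the original
#'   class codes.
#' @export
predictProba <- function(ensemble, X) {
  s <- rawScores(ensemble, X)
  p <- exp(s - apply(s, 1, max))
  p <- p / rowSums(p)
  colnames(p) <- as.character(ensemble@classLevels)
  p
}

#' @rdname predictProba
#' @return `predictClass`: integer labels in the original class codes.
#' @export
predictClass <- function(ensemble, X) {
  p <- predictProba(ensemble, X)
  ensemble@classLevels[max.col(p, ties.method = "first")]
}

#' @rdname predictProba
#' @return `predictValue`: raw predictions for the squared-error
#'   objective.
#' @export
predictValue <- function(ensemble, X) rawScores(ensemble, X)[, 1]

#' Feature importance of a boosted ensemble
#'
#' @param ensemble a [BoostedEnsemble-class].
#' @return data.frame with per-feature total split `gain` and split
#'   `frequency`, sorted by gain.
#' @export
featureImportance <- function(ensemble) {
  gain <- numeric(ensemble@nFeatures)
  freq <- numeric(ensemble@nFeatures)
  for (round_ in ensemble@trees)
    for (nodes in round_) {
      internal <- nodes[, "feature"] != 0
      if (!any(internal)) next
      f <- nodes[internal, "feature"]
      g <- nodes[internal, "gain"]
      for (i in seq_along(f)) {
        gain[f[i]] <- gain[f[i]] + g[i]
        freq[f[i]] <- freq[f[i]] + 1
      }
    }
  out <- data.frame(feature = seq_len(ensemble@nFeatures),
                    gain = gain, frequency = freq)
  out[order(-out$gain), ]
}

setMethod("show", "BoostedEnsemble", function(object) {
  cat(sprintf("BoostedEnsemble: %d rounds x %d class(es), depth <= %d, eta %.3g\n",
              length(object@trees), max(1L, length(object@classLevels)),
              object@params@maxDepth, object@params@eta))
})
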