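## Isomap spectral reconstruction: k-NN graph, all-pairs geodesic
## (shortest-path) distances, classical MDS on the double-centered
## squared distance matrix, RMSE-based choice of the embedding dimension,
## and a Nystrom-style out-of-sample extension.

#' Build a symmetrized k-nearest-neighbor graph
#'
#' Each point is connected to its `k` nearest Euclidean neighbors; the
#' edge set is symmetrized by union (an edge is kept if either endpoint
#' selects the other). Ties in distance are broken deterministically in
#' favor of the smaller index. Zero distances (duplicate points) are
#' floored at 1e-12 so edge weights stay strictly positive.
#'
#' @param X numeric matrix of points (rows).
#' @param k neighbors per node, `1 <= k < nrow(X)`.
#' @return a [NeighborGraph-class].
#' @export
buildKnnGraph <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  D <- as.matrix(dist(X))
  pairs <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])            # stable: smaller index wins ties
    nb <- seq_len(n)[-i][ord][seq_len(k)]
    pairs <- rbind(pairs, cbind(i, nb))
  }
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  w <- pmax(D[pairs], 1e-12)
  edges <- cbind(i = pairs[, 1], j = pairs[, 2], weight = w)
  new("NeighborGraph", n = n, k = k, edges = edges)
}

asIgraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph@n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(graph@edges[, 1:2, drop = FALSE])))
  igraph::E(g)$weight <- graph@edges[, 3]
  g
}

#' All-pairs geodesic distances on a neighbor graph
#'
#' Shortest-path distances along the graph (Dijkstra per source, via
#' igraph). Disconnected node pairs yield `Inf`.
#'
#' @param graph a [NeighborGraph-class].
#' @return symmetric n x n matrix with zero diagonal.
#' @export
geodesicDistances <- function(graph) {
  g <- asIgraph(graph)
  D <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(D) <- NULL
  D
}

## add minimal Euclidean bridges until the graph is connected
bridgeComponents <- function(graph, X) {
  repeat {
    comp <- igraph::components(asIgraph(graph))
    if (comp$no == 1L) return(graph)
    D <- as.matrix(dist(X))
    same <- outer(comp$membership, comp$membership, "==")
    D[same] <- Inf
    idx <- which(D == min(D), arr.ind = TRUE)[1, ]
    e <- c(min(idx), max(idx))
    graph@edges <- rbind(graph@edges,
                         c(e[1], e[2], max(D[idx[1], idx[2]], 1e-12)))
  }
}

#' Classical multidimensional scaling
#'
#' Double-centers the squared distance matrix, `B = -1/2 * H D^2 H`, and
#' extracts the top-`Z` eigenpairs. Coordinates are
#' `Y = V_Z diag(max(F, 0))^{1/2}`; eigenvector signs are fixed so the
#' largest-magnitude entry of each column is positive.
#'
#' @param D symmetric distance matrix with zero diagonal (distances, not
#'   squares).
#' @param Z number of components, `1 <= Z <= nrow(D)`.
#' @return list with `values` (all eigenvalues, descending), `vectors`
#'   (all sign-fixed unit eigenvectors), `Y` (n x Z coordinates) and
#'   `nClipped` (negative eigenvalues among the first Z).
#' @export
classicalMDS <- function(D, Z) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D < 0)) stop("D must be nonnegative")
  if (Z < 1 || Z > n) stop("Z must be in [1, n]")
  D2 <- D^2
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (c_ in seq_len(ncol(V))) {
    m <- which.max(abs(V[, c_]))
    if (V[m, c_] < 0) V[, c_] <- -V[, c_]
  }
  vals <- e$values
  Y <- V[, seq_len(Z), drop = FALSE] %*%
    diag(sqrt(pmax(vals[seq_len(Z)], 0)), Z, Z)
  list(values = vals, vectors = V, Y = Y,
       nClipped = sum(vals[seq_len(Z)] < 0))
}

#' Fit an Isomap embedding
#'
#' @param X points (rows) in the preprocessed spectral space.
#' @param k neighbors for the graph (default 10).
#' @param Z embedding dimensionality.
#' @param onDisconnect `"error"` (default) or `"bridge"`: bridge mode
#'   connects components through their single shortest inter-component
#'   Euclidean link instead of failing.
#' @return an [IsomapModel-class].
#' @export
isomapFit <- function(X, k = 10L, Z = 10L,
                      onDisconnect = c("error", "bridge")) {
  X <- as.matrix(X)
  onDisconnect <- match.arg(onDisconnect)
  Z <- as.integer(Z)
  if (Z < 1 || Z > nrow(X) - 1L) stop("Z must be in [1, n - 1]")
  graph <- buildKnnGraph(X, k)
  DG <- geodesicDistances(graph)
  if (any(!is.finite(DG))) {
    if (onDisconnect == "error")
      stop("neighbor graph is disconnected; increase k or use ",
           "onDisconnect = 'bridge'")
    graph <- bridgeComponents(graph, X)
    DG <- geodesicDistances(graph)
  }
  mds <- classicalMDS(DG, Z)
  new("IsomapModel", X = X, graph = graph, DG = DG, evals = mds$values,
      evecs = mds$vectors, Y = mds$Y, k = as.integer(k), Z = Z,
      nClipped = as.integer(mds$nClipped))
}

#' @rdname embedding
#' @export
setMethod("embedding", "IsomapModel", function(object, Z) {
  if (missing(Z)) Z <- object@Z
  if (Z > ncol(object@evecs)) stop("Z exceeds stored components")
  object@evecs[, seq_len(Z), drop = FALSE] %*%
    diag(sqrt(pmax(object@evals[seq_len(Z)], 0)), Z, Z)
})

#' Out-of-sample Isomap coordinates (Nystrom extension)
#'
#' Geodesic distances from each new point to all training points are
#' approximated through its `k` nearest training neighbors,
#' `g(x, j) = min_u d(x, u) + DG[u, j]`, then projected onto the stored
#' eigenbasis. A new point equal to a training point reproduces that
#' point's training coordinates exactly (its zero-distance anchor routes
#' all paths through itself).
#'
#' @param model a fitted [IsomapModel-class].
#' @param Xnew matrix of new points in the same preprocessed space.
#' @param Z number of coordinates (defaults to the fitted `Z`).
#' @return matrix `nrow(Xnew) x Z`.
#' @export
isomapTransform <- function(model, Xnew, Z = model@Z) {
  Xnew <- as.matrix(Xnew)
  if (Z > ncol(model@evecs)) stop("Z exceeds stored components")
  if (ncol(Xnew) != ncol(model@X))
    stop("Xnew has ", ncol(Xnew), " features, model expects ", ncol(model@X))
  n <- nrow(model@X)
  mu <- rowMeans(model@DG^2)
  vals <- model@evals[seq_len(Z)]
  V <- model@evecs[, seq_len(Z), drop = FALSE]
  scale <- ifelse(vals > 0, 1 / (2 * sqrt(vals)), 0)
  Ynew <- matrix(0, nrow(Xnew), Z)
  for (r in seq_len(nrow(Xnew))) {
    d <- sqrt(colSums((t(model@X) - Xnew[r, ])^2))
    anchors <- order(d)[seq_len(model@k)]
    g <- do.call(pmin, lapply(anchors, function(u) d[u] + model@DG[u, ]))
    Ynew[r, ] <- as.vector(crossprod(V, mu - g^2)) * scale
  }
  Ynew
}

#' Reconstruction RMSE of an embedding dimensionality
#'
#' Root-mean-square discrepancy, over all pairs `i < j`, between the
#' geodesic distance `DG[i, j]` and the Euclidean distance of the first
#' `Z` embedding coordinates.
#'
#' @param model a fitted [IsomapModel-class].
#' @param Z number of leading components to evaluate.
#' @return scalar RMSE (distance units of the input space).
#' @export
reconstructionRMSE <- function(model, Z) {
  if (Z < 1 || Z > ncol(model@evecs)) stop("Z must be in [1, n]")
  Y <- embedding(model, Z)
  dg <- model@DG[lower.tri(model@DG)]
  dy <- as.vector(dist(Y))
  sqrt(mean((dg - dy)^2))
}

#' Choose the embedding dimensionality by reconstruction RMSE
#'
#' Fits one Isomap model at the largest candidate `Z` and evaluates the
#' reconstruction RMSE over the whole candidate range; the smallest `Z`
#' attaining the minimum wins.
#'
#' @inheritParams isomapFit
#' @param zRange candidate dimensionalities (default `1:20`).
#' @param rmseTol absolute tolerance when comparing RMSE values: the
#'   smallest `Z` within `rmseTol` of the minimum wins, so numerically
#'   indistinguishable tail values do not inflate the chosen dimension.
#' @return list with `Z` (the argmin), `rmse` (the full curve, named by
#'   `zRange`) and `model` (fitted at `max(zRange)`).
#' @export
selectComponents <- function(X, k = 10L, zRange = 1:20,
                             onDisconnect = c("error", "bridge"),
                             rmseTol = 1e-8) {
  X <- as.matrix(X)
  if (any(zRange < 1) || any(zRange > nrow(X) - 1L))
    stop("zRange must lie within [1, n - 1]")
  model <- isomapFit(X, k, max(zRange), match.arg(onDisconnect))
  curve <- vapply(zRange, function(z) reconstructionRMSE(model, z),
                  numeric(1))
  names(curve) <- zRange
  list(Z = zRange[which(curve <= min(curve) + rmseTol)[1]],
       rmse = curve, model = model)
}

setMethod("show", "IsomapModel", function(object) {
  cat(sprintf(paste0("IsomapModel: %d points, k = %d, Z = %d",
                     " (%d negative eigenvalues clipped)\n"),
              nrow(object@X), object@k, object@Z, object@nClipped))
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d nodes, k = %d, %d undirected edges\n",
              object@n, object@k, nrow(object@edges)))
})
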