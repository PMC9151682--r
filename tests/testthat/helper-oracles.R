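## Independent reference implementations used only to check the package.

## Floyd-Warshall all-pairs shortest paths from a NeighborGraph
floydWarshall <- function(graph) {
  n <- graph@n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  e <- graph@edges
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1]; j <- e[r, 2]
    D[i, j] <- min(D[i, j], e[r, 3])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  D
}

## exhaustive second-order split search over all (feature, threshold)
## candidates; mirrors the documented tie-break (lower feature, lower
## threshold)
exhaustiveBestSplit <- function(X, g, h, lambda = 0, gamma = 0,
                               minChildWeight = 0) {
  best <- NULL
  G <- sum(g); H <- sum(h)
  parent <- G^2 / (H + lambda)
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      left <- X[, f] < thr
      GL <- sum(g[left]); HL <- sum(h[left])
      GR <- G - GL; HR <- H - HL
      if (HL < minChildWeight || HR < minChildWeight) next
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent) -
        gamma
      if (gain > 0 && (is.null(best) || gain > best$gain))
        best <- list(feature = f, threshold = thr, gain = gain)
    }
  }
  best
}

## random graph as a NeighborGraph (not necessarily kNN-shaped)
randomGraph <- function(n, pEdge = 0.3) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < pEdge
  ## always keep a spanning path so the graph is connected
  path <- cbind(seq_len(n - 1), 2:n)
  e <- unique(rbind(pairs[keep, , drop = FALSE], path))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  edges <- cbind(i = e[, 1], j = e[, 2],
                 weight = runif(nrow(e), 0.1, 2))
  new("NeighborGraph", n = as.integer(n), k = 1L, edges = edges)
}

## small labeled spectra fixture
tinySpectra <- function(nClasses = 3, nPerClass = 4, nBands = 16, seed = 1) {
  p <- makeClassProfiles(nClasses, nBands, c(400, 1000), seed = seed)
  simulateSpectra(p, nPerClass, scatterModel(), seed = seed + 1)
}
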