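test_that("kNN graphs match a brute-force neighbor oracle", {
  set.seed(13)
  X <- matrix(rnorm(50 * 4), 50, 4)
  k <- 4
  g <- buildKnnGraph(X, k)
  D <- as.matrix(dist(X))
  ## oracle: exhaustive sort per point, union-symmetrized
  want <- matrix(FALSE, 50, 50)
  for (i in 1:50) {
    nb <- setdiff(order(D[i, ]), i)[1:k]
    want[i, nb] <- TRUE
  }
  want <- want | t(want)
  got <- matrix(FALSE, 50, 50)
  got[g@edges[, 1:2]] <- TRUE
  got <- got | t(got)
  expect_identical(got, want)
  expect_true(all(g@edges[, 3] > 0))
  expect_true(all(g@edges[, 1] < g@edges[, 2]))  # no self-edges
})

test_that("kNN graph handles collinear points and the complete graph", {
  X <- matrix(c(0, 1, 3), 3, 1)
  g <- buildKnnGraph(X, 1)
  ## 0-1 mutual; 3's nearest is 1 -> kept by union
  expect_equal(g@edges[, 1:2], cbind(i = c(1, 2), j = c(2, 3)))
  gFull <- buildKnnGraph(matrix(rnorm(20), 10, 2), 9)
  expect_equal(nrow(gFull@edges), choose(10, 2))
  D <- as.matrix(dist(matrix(gFull@edges[, 3])))
  expect_error(buildKnnGraph(X, 3), "k must satisfy")
})

test_that("geodesic distances agree exactly with Floyd-Warshall", {
  ## path graph: d(1,3) = 2
  path <- new("NeighborGraph", n = 3L, k = 1L,
              edges = cbind(i = c(1, 2), j = c(2, 3), weight = c(1, 1)))
  expect_equal(geodesicDistances(path)[1, 3], 2)
  ## complete metric graph: direct edges optimal
  set.seed(14)
  P <- matrix(rnorm(12), 6, 2)
  g <- buildKnnGraph(P, 5)
  expect_equal(geodesicDistances(g), as.matrix(dist(P)), ignore_attr = TRUE)
  ## randomized suite vs the oracle
  set.seed(15)
  for (rep in 1:100) {
    gr <- randomGraph(sample(5:30, 1), runif(1, 0.1, 0.5))
    DG <- geodesicDistances(gr)
    expect_equal(DG, floydWarshall(gr), tolerance = 1e-12)
    expect_equal(DG, t(DG))
    expect_true(all(diag(DG) == 0))
  }
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  ## collinear points: 1-D coordinates up to sign and centering
  x <- c(0, 1, 2, 3)
  D <- as.matrix(dist(x))
  m <- classicalMDS(D, 1)
  got <- as.vector(m$Y)
  expect_equal(abs(got - mean(got)), abs(x - mean(x)), tolerance = 1e-10)
  ## planar points: pairwise distances reproduced at Z = 2
  set.seed(16)
  P <- matrix(rnorm(30), 15, 2)
  m2 <- classicalMDS(as.matrix(dist(P)), 2)
  expect_lt(max(abs(dist(m2$Y) - dist(P))), 1e-8)
  ## eigenvalues match a dense eigendecomposition of the centered matrix
  D2 <- as.matrix(dist(P))^2
  H <- diag(15) - 1 / 15
  B <- -0.5 * H %*% D2 %*% H
  expect_equal(m2$values, eigen(B, symmetric = TRUE)$values,
               tolerance = 1e-9)
  ## agreement with the standard principal-coordinates routine
  ref <- stats::cmdscale(as.matrix(dist(P)), k = 2)
  expect_equal(abs(m2$Y), abs(ref), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(classicalMDS(matrix(c(0, 1, 2, 0), 2, 2), 1), "symmetric")
})

test_that("complete-graph Isomap degenerates to principal coordinates", {
  set.seed(17)
  ## points in a 3-d affine subspace of a 10-d space
  basis <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  P <- matrix(rnorm(60), 20, 3) %*% t(basis) + 5
  model <- isomapFit(P, k = 19, Z = 3)
  expect_lt(max(abs(dist(model@Y) - dist(P))), 1e-8)
  expect_equal(model@nClipped, 0L)
  expect_lt(reconstructionRMSE(model, 3), 1e-8)
})

test_that("Isomap unrolls a noiseless 1-D curve embedded in 125-D", {
  set.seed(18)
  t_ <- seq(0, 3 * pi, length.out = 200)
  ## a curling curve lifted into 125 dimensions by a random linear map
  curve3 <- cbind(cos(t_), sin(t_), 0.5 * t_)
  lift <- matrix(rnorm(3 * 125, sd = 0.3), 3, 125)
  X <- curve3 %*% lift
  model <- isomapFit(X, k = 5, Z = 1)
  expect_gt(abs(cor(model@Y[, 1], t_, method = "spearman")), 0.99)
})

test_that("a hand-traced 5-point Isomap matches throughout", {
  ## 5 points on a line, k = 1: the graph is the path, geodesics are the
  ## coordinate gaps, and classical MDS recovers the line
  x <- c(0, 1, 2, 4, 7)
  model <- isomapFit(cbind(x), k = 1, Z = 1)
  DG <- outer(x, x, function(a, b) abs(a - b))
  expect_equal(model@DG, DG, ignore_attr = TRUE)
  got <- as.vector(model@Y)
  expect_equal(abs(got - mean(got)), abs(x - mean(x)), tolerance = 1e-8)
  ## hand-summed RMSE at Z = 1 is 0 (exactly embeddable)
  expect_lt(reconstructionRMSE(model, 1), 1e-8)
})

test_that("out-of-sample transform is self-consistent and interpolates", {
  set.seed(19)
  t_ <- seq(0, 2 * pi, length.out = 60)
  X <- cbind(cos(t_), sin(t_), t_)
  model <- isomapFit(X, k = 4, Z = 2)
  Yback <- isomapTransform(model, X)
  expect_lt(max(abs(Yback - model@Y)), 1e-6)
  ## duplicating training point 7 reproduces row 7
  expect_equal(isomapTransform(model, X[7, , drop = FALSE])[1, ],
               model@Y[7, ], tolerance = 1e-8)
  ## midpoint of two adjacent curve points embeds between them
  mid <- (X[20, ] + X[21, ]) / 2
  ymid <- isomapTransform(model, rbind(mid), Z = 1)[1, 1]
  lo <- min(model@Y[20:21, 1]); hi <- max(model@Y[20:21, 1])
  expect_gte(ymid, lo - 1e-8)
  expect_lte(ymid, hi + 1e-8)
  expect_error(isomapTransform(model, X[1:2, ], Z = 99), "exceeds")
})

test_that("reconstruction RMSE decreases in Z and drives selection", {
  set.seed(20)
  basis <- qr.Q(qr(matrix(rnorm(24), 8, 3)))
  P <- matrix(rnorm(90), 30, 3) %*% t(basis)
  sel <- selectComponents(P, k = 29, zRange = 1:6)
  ## exact intrinsic dimension 3: curve hits ~0 there and Z* = 3
  expect_equal(sel$Z, 3)
  expect_lt(sel$rmse[["3"]], 1e-8)
  expect_true(all(diff(sel$rmse) <= 1e-10))
  ## curve values equal individually recomputed RMSE calls
  for (z in 1:6)
    expect_equal(sel$rmse[[as.character(z)]],
                 reconstructionRMSE(sel$model, z))
})

test_that("embedding is permutation-invariant up to sign", {
  set.seed(22)
  X <- matrix(rnorm(40 * 6), 40, 6)
  perm <- sample(40)
  mA <- isomapFit(X, k = 6, Z = 2, onDisconnect = "bridge")
  mB <- isomapFit(X[perm, ], k = 6, Z = 2, onDisconnect = "bridge")
  DA <- as.matrix(dist(mA@Y))[perm, perm]
  DB <- as.matrix(dist(mB@Y))
  expect_equal(DA, DB, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("disconnected graphs error by default and bridge on request", {
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 100), 10, 2))
  expect_error(isomapFit(X, k = 2, Z = 1), "disconnected")
  m <- isomapFit(X, k = 2, Z = 1, onDisconnect = "bridge")
  expect_true(all(is.finite(m@DG)))
})

test_that("persisted Isomap models restore with identical transforms", {
  set.seed(36)
  X <- matrix(rnorm(40 * 5), 40, 5)
  model <- isomapFit(X, k = 6, Z = 3, onDisconnect = "bridge")
  path <- withr::local_tempfile(fileext = ".rds")
  saveIsomapModel(model, path)
  back <- readIsomapModel(path)
  Xnew <- matrix(rnorm(10), 2, 5)
  expect_identical(isomapTransform(back, Xnew), isomapTransform(model, Xnew))
  expect_identical(back@Y, model@Y)
})
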