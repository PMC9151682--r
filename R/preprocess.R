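## The "MS" preprocessing stage: multiplicative scatter correction (MSC)
## followed by weighted moving-window smoothing. MSC regresses every
## spectrum on a reference spectrum across bands (x ~ offset + slope*ref,
## ordinary least squares) and inverts the fit, (x - offset)/slope,
## removing additive baseline and multiplicative gain distortions.

#' Construct a moving-window smoothing kernel
#'
#' @param n half width in bands; the window spans `2n + 1` bands.
#' @param kind `"uniform"` (all weights `1/(2n+1)`) or `"triangular"`
#'   (weights decaying linearly to the window edge).
#' @param weights optional explicit nonnegative weights of length
#'   `2n + 1`; normalized to sum to one.
#' @return a [SmoothSpec-class].
#' @export
smoothSpec <- function(n = 2L, kind = c("uniform", "triangular"),
                       weights = NULL) {
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  if (is.null(weights)) {
    kind <- match.arg(kind)
    weights <- switch(kind,
                      uniform = rep(1, 2L * n + 1L),
                      triangular = (n + 1) - abs(seq(-n, n)))
  } else {
    kind <- "custom"
    if (length(weights) != 2L * n + 1L)
      stop("weights must have length 2n + 1 = ", 2L * n + 1L)
    if (any(weights < 0) || sum(weights) <= 0)
      stop("weights must be nonnegative with positive sum")
  }
  new("SmoothSpec", n = n, weights = weights / sum(weights), kind = kind)
}

## per-sample OLS of x against ref across bands
mscCoefficients <- function(X, ref) {
  vr <- sum((ref - mean(ref))^2)
  if (vr < .Machine$double.eps * length(ref))
    stop("degenerate MSC reference: zero variance across bands")
  refC <- ref - mean(ref)
  slope <- as.vector(X %*% refC - rowMeans(X) * sum(refC)) / vr
  bad <- which(abs(slope) < 1e-12)
  if (length(bad))
    stop("degenerate MSC fit: sample ", bad[1],
         " has slope below 1e-12 against the reference")
  offset <- unname(rowMeans(X)) - slope * mean(ref)
  list(offset = offset, slope = unname(slope))
}

#' Fit multiplicative scatter correction
#'
#' @param x a [SpectraSet-class] or samples x bands matrix.
#' @param reference `"mean"` (per-band mean of `x`) or an explicit
#'   reference spectrum.
#' @return an [MSCModel-class] holding the reference and the per-sample
#'   `(offset, slope)` OLS estimates.
#' @export
mscFit <- function(x, reference = "mean") {
  X <- if (is(x, "SpectraSet")) reflectance(x) else as.matrix(x)
  if (nrow(X) < 1) stop("need at least one sample")
  ref <- if (identical(reference, "mean")) colMeans(X) else as.numeric(reference)
  if (length(ref) != ncol(X))
    stop("reference length must equal the band count")
  cf <- mscCoefficients(X, ref)
  new("MSCModel", reference = ref, offset = cf$offset, slope = cf$slope)
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum is refitted against the model's (training) reference and
#' corrected as `(x - offset) / slope`. Held-out spectra are therefore
#' always corrected against the training reference, never their own mean.
#'
#' @param model an [MSCModel-class].
#' @param x a [SpectraSet-class] or samples x bands matrix.
#' @return object of the same kind as `x`, corrected.
#' @export
mscApply <- function(model, x) {
  X <- if (is(x, "SpectraSet")) reflectance(x) else as.matrix(x)
  if (ncol(X) != length(model@reference))
    stop("band count does not match the fitted MSC reference")
  cf <- mscCoefficients(X, model@reference)
  out <- (X - cf$offset) / cf$slope
  if (is(x, "SpectraSet")) setSpectra(x, out) else out
}

## dense (bands x bands) smoothing operator with shrink-and-renormalize
## edges: near the spectrum ends the window is truncated and the
## remaining weights rescaled, so no reflectance is invented beyond the
## measured range and constants are preserved everywhere.
smoothingMatrix <- function(nBands, spec) {
  n <- spec@n
  W <- matrix(0, nBands, nBands)
  for (k in seq_len(nBands)) {
    j <- max(1L, k - n):min(nBands, k + n)
    wt <- spec@weights[j - k + n + 1L]
    W[k, j] <- wt / sum(wt)
  }
  W
}

#' Weighted moving-window smoothing
#'
#' Replaces band `k` by the normalized weighted mean over the window
#' `k-n .. k+n`. Edges shrink the window and renormalize the weights.
#'
#' @param x a [SpectraSet-class] or samples x bands matrix.
#' @param spec a [smoothSpec()].
#' @return smoothed object of the same kind as `x` (same band count).
#' @export
movingWindowSmooth <- function(x, spec = smoothSpec()) {
  X <- if (is(x, "SpectraSet")) reflectance(x) else as.matrix(x)
  if (2L * spec@n + 1L > ncol(X))
    stop("smoothing window (", 2L * spec@n + 1L,
         " bands) is wider than the spectrum (", ncol(X), " bands)")
  out <- X %*% t(smoothingMatrix(ncol(X), spec))
  if (is(x, "SpectraSet")) setSpectra(x, out) else out
}

#' Fit-and-apply the MS stage (MSC then smoothing)
#'
#' Fits MSC with the mean reference of `x`, corrects `x`, then smooths.
#' The fitted stage is returned alongside so held-out spectra can be
#' transformed against the training reference with [applyMSTransform()].
#'
#' @param x a [SpectraSet-class].
#' @param smooth a [smoothSpec()].
#' @return a list with elements `spectra` (the transformed
#'   [SpectraSet-class]) and `transform` (an [MSTransform-class]).
#' @export
msTransform <- function(x, smooth = smoothSpec()) {
  model <- mscFit(x, "mean")
  tr <- new("MSTransform", msc = model, smooth = smooth)
  list(spectra = applyMSTransform(tr, x), transform = tr)
}

#' @rdname msTransform
#' @param transform an [MSTransform-class] from a previous [msTransform()].
#' @export
applyMSTransform <- function(transform, x) {
  movingWindowSmooth(mscApply(transform@msc, x), transform@smooth)
}
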