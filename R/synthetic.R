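## Synthetic grass-spectra generator. Class base curves share the
## vegetation landmarks every green canopy shows (green-reflectance bump
## near 550 nm, chlorophyll absorption trough near 680 nm, the red-edge
## rise over 690-750 nm, a NIR plateau, and a water-absorption dip near
## 970 nm); classes differ only in landmark amplitudes, which mirrors
## field observations that peak/trough POSITIONS coincide across species.

#' Run code with a private RNG stream
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so package randomness never perturbs user code.
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Class-specific smooth reflectance profiles
#'
#' Generates `nClasses` vegetation-like base curves on a common
#' wavelength grid. Landmark positions are fixed across classes;
#' per-class amplitudes (visible baseline, green-peak height, chlorophyll
#' trough depth, NIR plateau level, 970 nm dip depth, red-edge width) are
#' drawn from a seeded RNG, so profiles are deterministic for a fixed
#' seed.
#'
#' @param nClasses number of classes (>= 2).
#' @param nBands number of spectral bands (>= 8).
#' @param wavelengthRange `(low, high)` in nm, low < high.
#' @param seed integer seed.
#' @return a list of `nClasses` profiles; each profile is a list with
#'   elements `classId`, `wavelengths`, `baseCurve` (in `[0, 1]`) and
#'   `featureParams`.
#' @examples
#' p <- makeClassProfiles(2, 64, c(400, 1000), seed = 1)
#' range(p[[1]]$baseCurve)
#' @export
makeClassProfiles <- function(nClasses = 15, nBands = 125,
                              wavelengthRange = c(400, 1000), seed = 1) {
  if (nClasses < 2) stop("nClasses must be >= 2")
  if (nBands < 8) stop("nBands must be >= 8")
  if (length(wavelengthRange) != 2 || wavelengthRange[1] >= wavelengthRange[2])
    stop("wavelengthRange must be (low, high) with low < high")
  w <- seq(wavelengthRange[1], wavelengthRange[2], length.out = nBands)
  withSeed(seed, {
    lapply(seq_len(nClasses), function(cl) {
      fp <- list(
        visBase    = runif(1, 0.03, 0.08),   # visible-range floor
        greenAmp   = runif(1, 0.04, 0.10),   # 550 nm bump height
        troughAmp  = runif(1, 0.025, 0.06),  # 680 nm absorption depth
        nirLevel   = runif(1, 0.32, 0.60),   # NIR plateau reflectance
        redEdgeMid = 715,                    # nm, fixed across classes
        redEdgeWidth = runif(1, 15, 22),     # nm; >= 15 keeps the rise
                                             # smooth on the 4.8 nm grid
        dipAmp     = runif(1, 0.02, 0.10),   # 970 nm water dip depth
        greenCenter = 550, troughCenter = 680, dipCenter = 970,
        greenWidth = 28, troughWidth = 14, dipWidth = 22)
      curve <- fp$visBase +
        fp$greenAmp * exp(-((w - fp$greenCenter) / fp$greenWidth)^2 / 2) -
        fp$troughAmp * exp(-((w - fp$troughCenter) / fp$troughWidth)^2 / 2) +
        (fp$nirLevel - fp$visBase) /
          (1 + exp(-(w - fp$redEdgeMid) / fp$redEdgeWidth)) -
        fp$dipAmp * exp(-((w - fp$dipCenter) / fp$dipWidth)^2 / 2)
      curve <- pmin(pmax(curve, 0.005), 0.995)
      list(classId = cl, wavelengths = w, baseCurve = curve,
           featureParams = fp)
    })
  })
}

#' Scatter/noise distortion model for simulated spectra
#'
#' Each simulated sample is `a + b * baseCurve + eps`: an additive
#' baseline shift `a ~ Normal(0, additiveOffsetSd)`, a multiplicative
#' gain `b ~ Uniform(multiplicativeSlopeRange)` and i.i.d. band noise
#' `eps ~ Normal(0, noiseSd)`. This affine-plus-noise family is exactly
#' the distortion class MSC inverts.
#'
#' @param additiveOffsetSd standard deviation of the baseline shift
#'   (reflectance units).
#' @param multiplicativeSlopeRange `(low, high)`, strictly positive.
#' @param noiseSd standard deviation of per-band noise (>= 0).
#' @return a list with the three fields, class `"scatterModel"`.
#' @export
scatterModel <- function(additiveOffsetSd = 0.01,
                         multiplicativeSlopeRange = c(0.85, 1.15),
                         noiseSd = 0.005) {
  if (any(multiplicativeSlopeRange <= 0))
    stop("multiplicative slopes must be strictly positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (additiveOffsetSd < 0) stop("additiveOffsetSd must be >= 0")
  structure(list(additiveOffsetSd = additiveOffsetSd,
                 multiplicativeSlopeRange = multiplicativeSlopeRange,
                 noiseSd = noiseSd),
            class = "scatterModel")
}

#' Simulate labeled spectra from class profiles
#'
#' @param profiles output of [makeClassProfiles()].
#' @param nPerClass samples per class (>= 1).
#' @param scatter a [scatterModel()].
#' @param seed integer seed; fixing it fixes every draw bit-for-bit.
#' @return a [SpectraSet-class] with `nPerClass * length(profiles)`
#'   samples in class order (class 1 first).
#' @examples
#' p <- makeClassProfiles(3, 32, seed = 1)
#' x <- simulateSpectra(p, 5, scatterModel(), seed = 7)
#' table(classLabels(x))
#' @export
simulateSpectra <- function(profiles, nPerClass, scatter = scatterModel(),
                            seed = 1) {
  if (length(profiles) == 0) stop("profiles must be a non-empty list")
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  nb <- length(profiles[[1]]$baseCurve)
  w <- profiles[[1]]$wavelengths
  withSeed(seed, {
    rows <- vector("list", length(profiles))
    for (ci in seq_along(profiles)) {
      base <- profiles[[ci]]$baseCurve
      a <- rnorm(nPerClass, 0, scatter$additiveOffsetSd)
      b <- runif(nPerClass, scatter$multiplicativeSlopeRange[1],
                 scatter$multiplicativeSlopeRange[2])
      eps <- matrix(rnorm(nPerClass * nb, 0, scatter$noiseSd), nPerClass, nb)
      rows[[ci]] <- a + b %o% base + eps
    }
    X <- do.call(rbind, rows)
    labels <- rep(vapply(profiles, `[[`, integer(1), "classId"),
                  each = nPerClass)
    SpectraSet(X, w, labels)
  })
}

#' The default synthetic grass benchmark
#'
#' Convenience wrapper producing the package's standard benchmark
#' shape: 15 species x 50 samples, 125 bands over 400-1000 nm, with the
#' default scatter model.
#'
#' @param seed integer seed; profile shapes and sample draws both derive
#'   from it.
#' @inheritParams simulateSpectra
#' @return a [SpectraSet-class] with 750 samples.
#' @export
simulateGrassBenchmark <- function(seed = 1, scatter = scatterModel()) {
  profiles <- makeClassProfiles(15, 125, c(400, 1000), seed = seed)
  simulateSpectra(profiles, 50, scatter, seed = seed + 1000L)
}
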