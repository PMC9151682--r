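#' Construct a SpectraSet
#'
#' @param reflectance numeric matrix, samples x bands.
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   increasing, length = band count.
#' @param labels optional integer class labels, one per sample (`NA`
#'   allowed for unlabeled samples).
#' @param sampleIds optional character sample identifiers; defaults to
#'   `S0001, S0002, ...`.
#' @return a [SpectraSet-class].
#' @examples
#' x <- SpectraSet(matrix(runif(6), 2, 3), c(450, 550, 650))
#' reflectance(x)
#' @export
SpectraSet <- function(reflectance, wavelengths, labels = NULL,
                       sampleIds = NULL) {
  reflectance <- as.matrix(reflectance)
  n <- nrow(reflectance)
  b <- ncol(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != b)
    stop("length(wavelengths) [", length(wavelengths),
         "] must equal the band count [", b, "]")
  if (anyNA(wavelengths) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (!all(is.finite(reflectance)))
    stop("reflectance contains non-finite values")
  if (is.null(sampleIds)) sampleIds <- sprintf("S%04d", seq_len(n))
  if (length(sampleIds) != n)
    stop("length(sampleIds) must equal the sample count")
  if (is.null(labels)) {
    labels <- rep(NA_integer_, n)
  } else {
    labels <- as.integer(labels)
    if (length(labels) != n)
      stop("length(labels) [", length(labels),
           "] must equal the sample count [", n, "]")
  }
  assay <- t(reflectance)
  dimnames(assay) <- list(sprintf("B%03d", seq_len(b)), sampleIds)
  se <- SummarizedExperiment(
    assays = list(reflectance = assay),
    rowData = DataFrame(wavelength = wavelengths),
    colData = DataFrame(label = labels, row.names = sampleIds))
  new("SpectraSet", se)
}

#' @rdname SpectraSet
#' @export
setMethod("wavelengths", "SpectraSet", function(x) rowData(x)$wavelength)

#' @rdname SpectraSet
#' @export
setMethod("reflectance", "SpectraSet", function(x) {
  m <- t(assay(x, "reflectance"))
  colnames(m) <- NULL
  m
})

#' @rdname SpectraSet
#' @export
setMethod("classLabels", "SpectraSet", function(x) colData(x)$label)

#' @rdname SpectraSet
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

setMethod("show", "SpectraSet", function(object) {
  w <- wavelengths(object)
  lab <- classLabels(object)
  nc <- length(unique(lab[!is.na(lab)]))
  cat(sprintf("SpectraSet: %d samples x %d bands (%.1f-%.1f nm)\n",
              ncol(object), nrow(object), min(w), max(w)))
  cat(sprintf("  labels: %s\n",
              if (nc == 0) "none" else sprintf("%d classes", nc)))
})

## internal: rebuild a SpectraSet with new reflectance, keeping metadata
setSpectra <- function(x, reflectance) {
  SpectraSet(reflectance, wavelengths(x), classLabels(x), sampleIds(x))
}
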