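#' @rdname SpectraSet
#' @param x a `SpectraSet` (or other object with spectra semantics).
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectraSet
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname SpectraSet
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpectraSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Embedding coordinates of a fitted model
#'
#' @param object a fitted model (e.g. [IsomapModel-class]).
#' @param Z number of leading components to return; defaults to the
#'   fitted dimensionality.
#' @return an n x Z coordinate matrix.
#' @export
setGeneric("embedding", function(object, Z) standardGeneric("embedding"))
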