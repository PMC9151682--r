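## Spectra exchange formats.
##
## CSV dialect: UTF-8, comma-separated, "." decimal. First column
## sample_id, second column label (may be empty = unlabeled), remaining
## columns named by wavelength. Reflectance and wavelengths are written
## with 17 and 10 significant digits respectively so read(write(x))
## reproduces x exactly.
##
## ENVI support is a documented minimal subset: interleave "bil", data
## types 4 (32-bit float) and 12 (16-bit unsigned), optional "header
## offset" and "wavelength = { ... }" block, byte order 0/1. That is all
## a spectra-extraction workflow needs; BIP/BSQ and the rest of the ENVI
## dialect are out of scope.

#' Write a SpectraSet to CSV
#'
#' @param x a [SpectraSet-class].
#' @param path file path or writable connection.
#' @return `invisible(path)`.
#' @seealso [readSpectraCSV()]
#' @export
writeSpectraCSV <- function(x, path) {
  stopifnot(is(x, "SpectraSet"))
  R <- reflectance(x)
  lab <- classLabels(x)
  header <- paste(c("sample_id", "label",
                    sprintf("%.17g", wavelengths(x))), collapse = ",")
  labTxt <- ifelse(is.na(lab), "", as.character(lab))
  body <- vapply(seq_len(nrow(R)), function(i) {
    paste(c(sampleIds(x)[i], labTxt[i], sprintf("%.17g", R[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SpectraSet from CSV
#'
#' @param path file path or connection in the dialect written by
#'   [writeSpectraCSV()].
#' @return a [SpectraSet-class].
#' @export
readSpectraCSV <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("spectra CSV needs a header row and >= 1 sample")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "sample_id" || header[2] != "label")
    stop("spectra CSV header must start with sample_id,label,<wavelengths>")
  w <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(w))
    stop("non-numeric wavelength in header column ",
         which(is.na(w))[1] + 2L)
  if (any(diff(w) <= 0))
    stop("wavelengths must be strictly increasing (violation at header column ",
         which(diff(w) <= 0)[1] + 3L, ")")
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != length(header)))
    stop("ragged row ", which(nc != length(header))[1] + 1L,
         ": expected ", length(header), " fields, found ",
         nc[nc != length(header)][1])
  ids <- vapply(parts, `[[`, character(1), 1L)
  labTxt <- vapply(parts, `[[`, character(1), 2L)
  labels <- suppressWarnings(as.integer(labTxt))
  labels[labTxt == ""] <- NA_integer_
  bad <- which(labTxt != "" & is.na(labels))
  if (length(bad))
    stop("non-integer label in row ", bad[1] + 1L)
  R <- matrix(NA_real_, length(parts), length(w))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-(1:2)]))
    if (anyNA(v))
      stop("non-numeric reflectance at row ", i + 1L, ", column ",
           which(is.na(v))[1] + 2L)
    R[i, ] <- v
  }
  SpectraSet(R, w, labels, ids)
}

## ---- ENVI BIL -------------------------------------------------------------

enviDataTypes <- list(
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE))

parseEnviHeader <- function(headerText) {
  txt <- paste(headerText, collapse = "\n")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ## join multi-line { ... } blocks
  joined <- character(0)
  buf <- ""
  inBlock <- FALSE
  for (ln in lines) {
    if (inBlock) {
      buf <- paste(buf, ln)
      if (grepl("}", ln, fixed = TRUE)) { joined <- c(joined, buf); inBlock <- FALSE }
    } else if (grepl("\\{", ln) && !grepl("}", ln, fixed = TRUE)) {
      buf <- ln; inBlock <- TRUE
    } else joined <- c(joined, ln)
  }
  h <- list()
  for (ln in joined) {
    if (!grepl("=", ln, fixed = TRUE)) next
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    key <- tolower(trimws(kv[1]))
    val <- trimws(kv[2])
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- as.numeric(trimws(strsplit(val, ",", fixed = TRUE)[[1]]))
    }
    h[[key]] <- val
  }
  for (k in c("samples", "lines", "bands", "data type", "byte order",
              "header offset"))
    if (!is.null(h[[k]])) h[[k]] <- as.integer(h[[k]])
  names(h) <- sub("data type", "data.type", names(h), fixed = TRUE)
  names(h) <- sub("byte order", "byte.order", names(h), fixed = TRUE)
  names(h) <- sub("header offset", "header.offset", names(h), fixed = TRUE)
  h
}

#' Read a minimal ENVI BIL cube
#'
#' @param headerPath path to the ENVI `.hdr` text header (or a character
#'   vector of header lines via `headerText`).
#' @param dataPath path to the binary payload; defaults to `headerPath`
#'   with the `.hdr` extension stripped.
#' @param headerText optional header lines, overriding `headerPath`.
#' @return a [HyperCube-class] with data decoded to
#'   `[line, sample, band]`.
#' @export
readENVI <- function(headerPath, dataPath = NULL, headerText = NULL) {
  if (is.null(headerText)) headerText <- readLines(headerPath)
  h <- parseEnviHeader(headerText)
  for (k in c("samples", "lines", "bands", "data.type", "interleave"))
    if (is.null(h[[k]]))
      stop("ENVI header is missing required field '", gsub("\\.", " ", k), "'")
  if (tolower(h$interleave) != "bil")
    stop("unsupported ENVI interleave '", h$interleave,
         "': only 'bil' is supported")
  dt <- enviDataTypes[[as.character(h$data.type)]]
  if (is.null(dt))
    stop("unsupported ENVI data type ", h$data.type,
         ": supported types are 4 (float32) and 12 (uint16)")
  if (is.null(h$byte.order)) h$byte.order <- 0L
  if (is.null(h$header.offset)) h$header.offset <- 0L
  if (is.null(dataPath))
    dataPath <- sub("\\.hdr$", "", headerPath)
  nvals <- h$samples * h$lines * h$bands
  expected <- nvals * dt$size + h$header.offset
  actual <- file.info(dataPath)$size
  if (is.na(actual) || actual != expected)
    stop("corrupt ENVI file: payload is ", actual, " bytes, header implies ",
         expected)
  con <- file(dataPath, "rb")
  on.exit(close(con))
  if (h$header.offset > 0) readBin(con, "raw", h$header.offset)
  endian <- if (h$byte.order == 1L) "big" else "little"
  v <- readBin(con, dt$what, n = nvals, size = dt$size,
               signed = dt$signed, endian = endian)
  ## BIL order: [line][band][sample] -> decode to [line, sample, band]
  a <- array(as.numeric(v), dim = c(h$samples, h$bands, h$lines))
  cube <- aperm(a, c(3, 1, 2))
  new("HyperCube", cube = cube, header = h)
}

#' Write a minimal ENVI BIL cube
#'
#' @param cube a [HyperCube-class] or a `[line, sample, band]` array.
#' @param basePath output path stem; writes `<basePath>` (binary) and
#'   `<basePath>.hdr`.
#' @param dataType ENVI data type code, 4 (float32) or 12 (uint16).
#' @param wavelengths optional band-center wavelengths recorded in the
#'   header.
#' @return `invisible(basePath)`.
#' @export
writeENVI <- function(cube, basePath, dataType = 4L, wavelengths = NULL) {
  if (is(cube, "HyperCube")) {
    if (is.null(wavelengths)) wavelengths <- cube@header$wavelength
    cube <- cube@cube
  }
  d <- dim(cube)
  stopifnot(length(d) == 3)
  dt <- enviDataTypes[[as.character(dataType)]]
  if (is.null(dt)) stop("unsupported ENVI data type ", dataType)
  hdr <- c("ENVI",
           paste("samples =", d[2]), paste("lines =", d[1]),
           paste("bands =", d[3]), "header offset = 0",
           paste("data type =", dataType), "interleave = bil",
           "byte order = 0")
  if (!is.null(wavelengths))
    hdr <- c(hdr, paste0("wavelength = { ",
                         paste(sprintf("%.10g", wavelengths), collapse = ", "),
                         " }"))
  writeLines(hdr, paste0(basePath, ".hdr"))
  v <- as.vector(aperm(cube, c(2, 3, 1)))  # [sample][band][line] fastest-first
  con <- file(basePath, "wb")
  on.exit(close(con))
  if (dataType == 12L) {
    iv <- as.integer(round(v))
    if (any(iv < 0 | iv > 65535)) stop("uint16 values must be in [0, 65535]")
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # two's complement for writeBin
    writeBin(iv, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  invisible(basePath)
}

#' Extract per-region mean spectra from a hyperspectral cube
#'
#' Row `s` of the result is the arithmetic per-band mean over the pixels
#' selected by `masks[[s]]`, mirroring the field workflow where the mean
#' reflectance of the pixels of one grass patch becomes that sample's
#' spectrum.
#'
#' @param cube a [HyperCube-class].
#' @param masks list of logical `lines x samples` matrices, one per
#'   output sample; each must select at least one pixel.
#' @param labels optional integer labels copied to the output.
#' @return a [SpectraSet-class] with one row per mask. Wavelengths come
#'   from the cube header when present, else band indices are used.
#' @export
extractMeanSpectra <- function(cube, masks, labels = NULL) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@cube)
  flat <- matrix(cube@cube, d[1] * d[2], d[3])  # pixel (line-major) x band
  out <- matrix(NA_real_, length(masks), d[3])
  for (s in seq_along(masks)) {
    m <- masks[[s]]
    if (!identical(dim(m), d[1:2]))
      stop("mask ", s, " has shape ", paste(dim(m), collapse = "x"),
           ", expected ", d[1], "x", d[2])
    sel <- which(as.vector(m))
    if (length(sel) == 0) stop("mask ", s, " selects no pixels")
    out[s, ] <- colMeans(flat[sel, , drop = FALSE])
  }
  w <- cube@header$wavelength
  if (is.null(w)) w <- seq_len(d[3])
  SpectraSet(out, w, labels)
}

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@cube)
  cat(sprintf("HyperCube: %d lines x %d samples x %d bands (%s)\n",
              d[1], d[2], d[3],
              if (is.null(object@header$interleave)) "?" else
                object@header$interleave))
})
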