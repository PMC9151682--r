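## Confusion-matrix evaluation for multiclass classifiers: overall
## accuracy, Cohen's kappa, and unweighted (macro) precision/recall/F1.

#' Confusion matrix counts
#'
#' @param yTrue,yPred integer labels in `1..nClasses`.
#' @param nClasses number of classes.
#' @return `nClasses x nClasses` count matrix; rows = true class,
#'   columns = predicted class.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses) {
  yTrue <- as.integer(yTrue)
  yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (any(c(yTrue, yPred) < 1 | c(yTrue, yPred) > nClasses))
    stop("labels must lie in 1..", nClasses)
  cm <- matrix(0L, nClasses, nClasses)
  for (i in seq_along(yTrue))
    cm[yTrue[i], yPred[i]] <- cm[yTrue[i], yPred[i]] + 1L
  dimnames(cm) <- list(true = seq_len(nClasses), pred = seq_len(nClasses))
  cm
}

#' @rdname metricsReport
#' @export
overallAccuracy <- function(counts) sum(diag(counts)) / sum(counts)

#' @rdname metricsReport
#' @export
cohensKappa <- function(counts) {
  n <- sum(counts)
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    ## single-class degenerate table: agreement is either perfect or not
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' @rdname metricsReport
#' @return `macroScores`: list with `precision`, `recall`, `f1`
#'   (unweighted class means) and the per-class vectors.
#' @export
macroScores <- function(counts) {
  tp <- diag(counts)
  rowTot <- rowSums(counts)  # true counts per class
  colTot <- colSums(counts)  # predicted counts per class
  present <- rowTot > 0 | colTot > 0
  if (any(!present))
    warning(sum(!present), " class(es) absent from both truth and ",
            "prediction dropped from macro averages")
  precision <- ifelse(colTot > 0, tp / colTot, 0)
  recall <- ifelse(rowTot > 0, tp / rowTot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(precision = mean(precision[present]),
       recall = mean(recall[present]),
       f1 = mean(f1[present]),
       perClassPrecision = precision, perClassRecall = recall,
       perClassF1 = f1)
}

#' Full multiclass evaluation report
#'
#' Computes the confusion matrix and all derived scores. Macro-F1 is the
#' unweighted mean of per-class F1 values (not the F1 of macro-P/R);
#' classes absent from both truth and prediction are dropped from macro
#' averages with a warning.
#'
#' @param yTrue,yPred integer labels in `1..nClasses`, or pass a
#'   precomputed count matrix as `counts`.
#' @param nClasses number of classes.
#' @param counts optional confusion count matrix replacing
#'   `yTrue`/`yPred`.
#' @return a [MetricsReport-class].
#' @examples
#' r <- metricsReport(c(1, 2, 2, 3), c(1, 2, 3, 3), nClasses = 3)
#' r
#' @export
metricsReport <- function(yTrue, yPred, nClasses, counts = NULL) {
  if (is.null(counts)) counts <- confusionCounts(yTrue, yPred, nClasses)
  m <- macroScores(counts)
  new("MetricsReport", confusion = counts,
      oa = overallAccuracy(counts), kappa = cohensKappa(counts),
      macroPrecision = m$precision, macroRecall = m$recall,
      macroF1 = m$f1)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport (%d classes, %d samples)\n",
                     "  OA %.4f | kappa %.4f | macro P %.4f",
                     " R %.4f F1 %.4f\n"),
              nrow(object@confusion), sum(object@confusion), object@oa,
              object@kappa, object@macroPrecision, object@macroRecall,
              object@macroF1))
})

#' Serialize a metrics report
#'
#' @param report a [MetricsReport-class].
#' @param path output CSV path for the scalar scores; the confusion
#'   matrix is written next to it as `<path>.confusion.csv`.
#' @return `invisible(path)`.
#' @export
writeMetricsCSV <- function(report, path) {
  df <- data.frame(metric = c("oa", "kappa", "macro_precision",
                              "macro_recall", "macro_f1"),
                   value = c(report@oa, report@kappa, report@macroPrecision,
                             report@macroRecall, report@macroF1))
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(as.data.frame(report@confusion),
                   paste0(path, ".confusion.csv"))
  invisible(path)
}
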