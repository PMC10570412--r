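# Multiclass evaluation: confusion matrix, accuracy, per-class
# precision / recall / F1, as reported per stage.

#' Confusion matrix for three-stage labels
#'
#' @param yTrue,yPred integer labels in \code{{0, 1, 2}}
#'   (normal/acute/chronic), equal length.
#' @return 3 x 3 integer matrix; entry (i, j) counts samples of true class
#'   i - 1 predicted as class j - 1.
#' @export
confusionMatrix <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("label vectors must have equal length")
  if (!all(yTrue %in% 0:2) || !all(yPred %in% 0:2))
    stop("labels must be in {0, 1, 2}")
  cm <- matrix(0L, 3, 3, dimnames = list(true = STAGES, predicted = STAGES))
  for (i in seq_along(yTrue))
    cm[yTrue[i] + 1L, yPred[i] + 1L] <- cm[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  cm
}

#' Overall accuracy from a confusion matrix
#'
#' Correct predictions over total predictions, as a fraction in [0, 1]
#' (multiply by 100 for display).
#'
#' @param confusion square count matrix, rows = true, columns = predicted.
#' @export
accuracyScore <- function(confusion) {
  n <- sum(confusion)
  if (n < 1) stop("empty confusion matrix")
  sum(diag(confusion)) / n
}

#' Per-class precision, recall and F1
#'
#' \code{precision = TP / column sum}, \code{recall = TP / row sum},
#' \code{f1 = 2PR / (P + R)}. A zero denominator yields 0 with a warning.
#'
#' @param confusion square count matrix.
#' @param classIdx 0-based class index.
#' @return Named numeric vector \code{c(precision, recall, f1)}.
#' @export
precisionRecallF1 <- function(confusion, classIdx) {
  i <- classIdx + 1L
  tp <- confusion[i, i]
  colSum <- sum(confusion[, i]); rowSum <- sum(confusion[i, ])
  if (colSum == 0 || rowSum == 0)
    warning("class ", classIdx, ": zero denominator, metric set to 0")
  p <- if (colSum > 0) tp / colSum else 0
  r <- if (rowSum > 0) tp / rowSum else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else {
    if (colSum > 0 && rowSum > 0) 0 else 0
  }
  c(precision = p, recall = r, f1 = f)
}

#' Build a full evaluation report
#'
#' @param yTrue,yPred integer labels in \code{{0, 1, 2}}.
#' @return An [EvalReport-class].
#' @export
evalReport <- function(yTrue, yPred) {
  cm <- confusionMatrix(yTrue, yPred)
  prf <- vapply(0:2, function(k) precisionRecallF1(cm, k), numeric(3))
  new("EvalReport", confusion = cm, accuracy = accuracyScore(cm),
      precision = stats::setNames(prf[1, ], STAGES),
      recall = stats::setNames(prf[2, ], STAGES),
      f1 = stats::setNames(prf[3, ], STAGES),
      nSamples = length(yTrue))
}

#' Serialise a report as JSON (plus the confusion matrix as CSV)
#'
#' Both raw counts and row-normalised rates of the confusion matrix are
#' included.
#'
#' @param report an [EvalReport-class].
#' @param jsonPath output JSON path; \code{NULL} to skip writing.
#' @param csvPath optional CSV path for the confusion counts.
#' @return The report as a list, invisibly if written.
#' @export
reportToJSON <- function(report, jsonPath = NULL, csvPath = NULL) {
  rates <- sweep(report@confusion, 1, pmax(rowSums(report@confusion), 1), "/")
  out <- list(n_samples = report@nSamples, accuracy = report@accuracy,
              confusion_counts = unname(apply(report@confusion, 1, identity,
                                              simplify = FALSE)),
              confusion_row_rates = unname(apply(rates, 1, identity,
                                                 simplify = FALSE)),
              precision = as.list(report@precision),
              recall = as.list(report@recall), f1 = as.list(report@f1))
  if (!is.null(csvPath))
    utils::write.csv(report@confusion, csvPath)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
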