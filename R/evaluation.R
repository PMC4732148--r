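# Class-imbalance-aware evaluation: confusion matrix, per-class
# precision/recall/F1 and the sample-weighted F1 headline metric.

#' Confusion matrix of window-level predictions
#'
#' Rows are actual classes and columns predicted classes, so the cell
#' (i, j) counts how often class i was classified as class j.
#'
#' @param actual integer vector of true 0-based labels.
#' @param predicted integer vector of predicted 0-based labels.
#' @param nClasses number of classes nc.
#' @return integer nc x nc matrix with dimnames "0".."nc-1".
#' @examples
#' confusionMatrix(c(0, 0, 1), c(0, 1, 1), 2)
#' @export
confusionMatrix <- function(actual, predicted, nClasses) {
  actual <- as.integer(actual); predicted <- as.integer(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have the same length")
  if (any(actual < 0L) || any(actual >= nClasses) ||
      any(predicted < 0L) || any(predicted >= nClasses))
    stop(sprintf("labels must lie in [0, %d)", nClasses))
  lev <- 0:(nClasses - 1L)
  cm <- table(factor(actual, levels = lev), factor(predicted, levels = lev))
  m <- matrix(as.integer(cm), nClasses, nClasses,
              dimnames = list(actual = lev, predicted = lev))
  m
}

# Per-class precision, recall and F1 with the zero-denominator convention
# (no predictions or no instances of a class -> that quantity is 0).
.classMetrics <- function(cm) {
  tp <- diag(cm)
  rowN <- rowSums(cm)   # actual counts n_i
  colN <- colSums(cm)   # predicted counts
  precision <- ifelse(colN > 0, tp / colN, 0)
  recall <- ifelse(rowN > 0, tp / rowN, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = as.integer(rownames(cm)), n = as.integer(rowN),
             weight = rowN / sum(cm), precision = precision,
             recall = recall, f1 = f1, row.names = NULL)
}

#' Sample-weighted F1 from a confusion matrix
#'
#' Class imbalance (the Null class can dominate three quarters of a
#' naturalistic recording) is countered by weighting each per-class F1 by
#' the class's sample proportion:
#' F1 = sum_i 2 w_i (precision_i * recall_i) / (precision_i + recall_i)
#' with w_i = n_i / N. A class with zero predicted or zero actual
#' instances contributes a per-class F1 of 0.
#'
#' @param cm square confusion matrix (rows = actual).
#' @return weighted F1 in [0, 1].
#' @examples
#' weightedF1(matrix(c(8, 1, 2, 9), 2))  # ~0.8496
#' @export
weightedF1 <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  rowN <- rowSums(cm); colN <- colSums(cm)
  precision <- ifelse(colN > 0, tp / colN, 0)
  recall <- ifelse(rowN > 0, tp / rowN, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  sum(rowN / sum(cm) * f1)
}

#' Evaluate a model on a batch of windows
#'
#' Predicts every window (argmax of the class distribution, ties to the
#' lowest index) and reports the confusion matrix, per-class metrics and
#' the sample-weighted F1. With \code{nullMode = "included"} all windows
#' are scored over all classes of the recording, the realistic setting
#' where most of the stream is Null. With \code{nullMode = "excluded"}
#' Null-labelled windows are removed and the gesture classes are scored
#' on their own; the model is expected to have been trained on the
#' gesture-only class set (see \code{\link{dropNullWindows}}), mirroring
#' the benchmark tasks that pose gesture recognition without a Null class.
#'
#' @param model a \linkS4class{HARModel}.
#' @param batch a \linkS4class{WindowBatch}. For \code{"excluded"} the
#'   labels must still use the original encoding (0 = Null) unless no
#'   Null windows are present.
#' @param nullMode "included" or "excluded".
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateModel <- function(model, batch, nullMode = c("included", "excluded")) {
  nullMode <- match.arg(nullMode)
  stopifnot(is(model, "HARModel"), is(batch, "WindowBatch"))
  nc <- model@spec@nClasses
  if (nullMode == "excluded" && any(batch@labels == 0L))
    batch <- dropNullWindows(batch)
  if (any(batch@labels >= nc))
    stop(sprintf(
      "batch labels exceed the model's %d classes (nc mismatch%s)", nc,
      if (nullMode == "excluded")
        "; excluded mode expects a model trained on the gesture-only set"
      else ""))
  pred <- predictClasses(model, batch)
  cm <- confusionMatrix(batch@labels, pred, nc)
  new("EvaluationReport", confusion = cm, perClass = .classMetrics(cm),
      weightedF1 = weightedF1(cm), nullMode = nullMode)
}

#' Write an evaluation report as delimited tables
#'
#' Writes \code{<prefix>-confusion.tsv} (rows = actual gesture, columns =
#' predicted gesture), \code{<prefix>-classes.tsv} (per-class metrics) and
#' \code{<prefix>-summary.txt} (one line with the weighted F1 and mode).
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param prefix output path prefix.
#' @return invisibly, the three paths.
#' @export
writeEvaluationReport <- function(report, prefix) {
  stopifnot(is(report, "EvaluationReport"))
  paths <- paste0(prefix, c("-confusion.tsv", "-classes.tsv", "-summary.txt"))
  utils::write.table(report@confusion, paths[1], sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(report@perClass, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("weighted_f1\t%.6f\tnull_mode\t%s",
                     report@weightedF1, report@nullMode), paths[3])
  invisible(paths)
}
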