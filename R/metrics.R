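#' Evaluation report from gold and predicted labels
#'
#' Computes accuracy, macro-averaged F1 (unweighted mean over classes of
#' `2PR/(P+R)`, 0 where undefined), the gold-by-predicted confusion
#' matrix, and accuracy within sentence-length buckets `[0,45)`, `[45,75)`
#' and `[75, Inf)` when token lengths are supplied.
#'
#' @param gold,predicted character vectors of labels.
#' @param classes ordered class names (rows/columns of the confusion
#'   matrix).
#' @param lengths optional integer vector of instance token counts.
#' @return object of class `eval_report`: list with `accuracy`,
#'   `macro_f1`, `confusion`, `per_class` (precision/recall/F1), and
#'   `length_buckets` (or `NULL`).
#' @export
eval_report <- function(gold, predicted, classes, lengths = NULL) {
  if (length(gold) != length(predicted)) stop("gold/predicted length mismatch")
  gold <- factor(gold, levels = classes)
  predicted <- factor(predicted, levels = classes)
  if (anyNA(gold) || anyNA(predicted)) stop("label outside the class set")
  confusion <- table(gold = gold, predicted = predicted)
  report_from_confusion(unclass(as.matrix(confusion)), classes,
                        lengths = lengths, correct = gold == predicted)
}

# shared core so a pre-tabulated confusion matrix can be scored directly
report_from_confusion <- function(confusion, classes, lengths = NULL,
                                  correct = NULL) {
  confusion <- as.matrix(confusion)
  dimnames(confusion) <- list(gold = classes, predicted = classes)
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  prec <- diag(confusion) / pmax(colSums(confusion), 1e-12)
  rec <- diag(confusion) / pmax(rowSums(confusion), 1e-12)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # classes absent from both gold and predictions carry F1 = 0
  buckets <- NULL
  if (!is.null(lengths) && !is.null(correct)) {
    cut_at <- cut(lengths, c(0, 45, 75, Inf), right = FALSE,
                  labels = c("[0,45)", "[45,75)", "[75,Inf)"))
    buckets <- tapply(correct, cut_at, mean)
  }
  structure(list(accuracy = acc, macro_f1 = mean(f1), confusion = confusion,
                 per_class = data.frame(class = classes, precision = prec,
                                        recall = rec, f1 = f1,
                                        row.names = NULL),
                 length_buckets = buckets, n = total),
            class = "eval_report")
}

#' Score a pre-tabulated confusion matrix
#'
#' Useful for auditing externally tabulated results: accuracy is
#' `trace/total` and macro-F1 is derived from the row/column margins.
#'
#' @param confusion square numeric matrix, gold in rows, predictions in
#'   columns.
#' @param classes optional class names; defaults to the matrix dimnames
#'   or `C1..Cn`.
#' @return an [eval_report()] object.
#' @export
confusion_report <- function(confusion, classes = NULL) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  classes <- classes %||% rownames(confusion) %||%
    paste0("C", seq_len(nrow(confusion)))
  report_from_confusion(confusion, classes)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy=%.4f  macro-F1=%.4f\n",
              x$n, x$accuracy, x$macro_f1))
  cat("confusion (gold x predicted):\n")
  print(x$confusion)
  if (!is.null(x$length_buckets)) {
    cat("accuracy by token-length bucket:\n")
    print(round(x$length_buckets, 4))
  }
  invisible(x)
}

#' Report the evaluation as plain lists (for JSON serialization)
#' @param report an [eval_report()].
#' @return nested list mirroring the report fields.
#' @export
report_as_list <- function(report) {
  list(accuracy = report$accuracy, macro_f1 = report$macro_f1, n = report$n,
       confusion = unname(apply(report$confusion, 1L, as.numeric,
                                simplify = FALSE)),
       classes = rownames(report$confusion),
       length_buckets = if (is.null(report$length_buckets)) NULL
                        else as.list(report$length_buckets))
}
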