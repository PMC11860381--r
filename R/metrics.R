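#' Binary classification report
#'
#' Confusion counts and the class-error metric used for model selection:
#' `class_error = 1 - (sensitivity + specificity) / 2`, the mean of the
#' false-positive and false-negative rates. `overall_accuracy` is defined
#' as `1 - class_error` in the stated context (calibration,
#' cross-validation or prediction), which is the convention behind every
#' reported "overall accuracy" in this workflow.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param positive The label counted as the positive class; everything else
#'   is negative.
#' @param context `"calibration"`, `"cross-validation"` or `"prediction"`.
#' @return A `"classification_report"`: list with `confusion` (2x2 matrix,
#'   truth in rows), `sensitivity`, `specificity`, `class_error`,
#'   `overall_accuracy`, `positive` and `context`.
#' @examples
#' evaluate(c("A", "A", "B", "B"), c("A", "B", "B", "B"), positive = "A")
#' @export
evaluate <- function(truth, predicted, positive,
                     context = c("calibration", "cross-validation",
                                 "prediction")) {
  context <- match.arg(context)
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  confusion <- matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(truth = c(positive, "other"),
                                      predicted = c(positive, "other")))
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  class_error <- 1 - (sensitivity + specificity) / 2
  structure(list(confusion = confusion,
                 sensitivity = sensitivity, specificity = specificity,
                 class_error = class_error,
                 overall_accuracy = 1 - class_error,
                 positive = positive, context = context),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> context: %s, positive: %s\n",
              x$context, x$positive))
  print(x$confusion)
  cat(sprintf("  sensitivity %.3f  specificity %.3f  class error %.1f%%  overall accuracy %.1f%%\n",
              x$sensitivity, x$specificity, 100 * x$class_error,
              100 * x$overall_accuracy))
  invisible(x)
}

#' @export
as.data.frame.classification_report <- function(x, ...) {
  data.frame(context = x$context, positive = x$positive,
             tp = x$confusion[1, 1], fn = x$confusion[1, 2],
             fp = x$confusion[2, 1], tn = x$confusion[2, 2],
             sensitivity = x$sensitivity, specificity = x$specificity,
             class_error = x$class_error,
             overall_accuracy = x$overall_accuracy)
}
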