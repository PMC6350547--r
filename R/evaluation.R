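#' Confusion matrix with columns as the actual class
#'
#' Builds the 4x4 confusion matrix under the convention that each column
#' indexes the actual category and each row the predicted one:
#' `counts[r, c]` is the number of samples of actual class c predicted
#' as r, so column sums are the per-class actual counts.
#'
#' @param predicted,actual Equal-length character vectors over
#'   `spect_classes()`.
#' @return Integer matrix (4 x 4) with dimnames
#'   `list(predicted = ..., actual = ...)`.
#' @export
confusion_matrix <- function(predicted, actual) {
  assert_that(length(predicted) == length(actual),
              "predicted and actual must have equal length")
  check_labels(predicted, "predicted label")
  check_labels(actual, "actual label")
  cm <- table(factor(predicted, levels = spect_classes()),
              factor(actual, levels = spect_classes()))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(predicted = spect_classes(),
                               actual = spect_classes()))
  cm
}

#' One-vs-rest counts and metrics for a single class
#'
#' Treats `class` as positive and the other three classes as negative,
#' extracts TP/TN/FP/FN from the confusion matrix, and computes
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' accuracy = (TP+TN)/(TP+FN+FP+TN), specificity = TN/(FP+TN) and
#' F1 = 2TP/(2TP+FP+FN). A metric whose denominator is zero is reported
#' as `NA` (undefined), never silently as 0 or 1.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param class One of `spect_classes()`.
#' @return An object of class `class_report`: list with `class`, the
#'   four counts and the five metrics.
#' @export
class_report <- function(cm, class) {
  check_labels(class, "class")
  i <- match(class, spect_classes())
  tp <- cm[i, i]
  fn <- sum(cm[, i]) - tp      # actual class i, predicted elsewhere
  fp <- sum(cm[i, ]) - tp      # predicted class i, actually elsewhere
  tn <- sum(cm) - tp - fn - fp
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(class = class, TP = tp, TN = tn, FP = fp, FN = fn,
                 recall = rate(tp, tp + fn),
                 precision = rate(tp, tp + fp),
                 accuracy = rate(tp + tn, tp + fn + fp + tn),
                 specificity = rate(tn, fp + tn),
                 f1 = rate(2 * tp, 2 * tp + fp + fn)),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report %s: TP=%d FP=%d FN=%d TN=%d | recall=%s precision=%s accuracy=%s specificity=%s F1=%s>\n",
              x$class, x$TP, x$FP, x$FN, x$TN,
              fmt_pc(x$recall), fmt_pc(x$precision), fmt_pc(x$accuracy),
              fmt_pc(x$specificity), fmt_pc(x$f1)))
  invisible(x)
}

# percentage with 2 decimals, half-even rounding; NA -> "undefined"
fmt_pc <- function(x) {
  if (is.na(x)) "undefined" else sprintf("%.2f", round(100 * x, 2))
}

#' Macro-averaged one-vs-rest precision
#'
#' Unweighted mean of the four per-class precisions; classes with
#' undefined precision (no predictions of that class) are excluded from
#' the mean and counted.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return List with `value` (NA when all four are undefined) and
#'   `n_undefined`.
#' @export
macro_precision <- function(cm) {
  prec <- vapply(spect_classes(),
                 function(cl) class_report(cm, cl)$precision, numeric(1))
  n_undef <- sum(is.na(prec))
  list(value = if (n_undef == 4L) NA_real_ else mean(prec, na.rm = TRUE),
       n_undefined = n_undef)
}

#' Evaluate a model on a test set
#'
#' Predictions are the argmax of the forward probabilities; the true
#' class of a (possibly mixed) sample is the argmax of its label vector.
#' Returns the confusion matrix, the four one-vs-rest class reports and
#' the macro-averaged metrics.
#'
#' @param model A `spect_net`.
#' @param test_set Nonempty list of `soft_sample` or `labeled_image`.
#' @param chunk Internal batching size for the forward passes.
#' @return An object of class `eval_result`: list with `cm`, `reports`
#'   (named by class), `macro` (macro-averaged recall/precision/
#'   accuracy/specificity/f1) and `n`.
#' @export
evaluate_model <- function(model, test_set, chunk = 100L) {
  assert_that(length(test_set) > 0, "test set is empty")
  n <- length(test_set)
  pred <- character(n)
  actual <- character(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    sub <- test_set[i:j]
    probs <- predict_proba(model, sub)
    pred[i:j] <- spect_classes()[apply(probs, 1L, which.max)]
    actual[i:j] <- vapply(sub, function(s) {
      if (!is.null(s$label_vec)) spect_classes()[which.max(s$label_vec)]
      else s$label
    }, character(1))
    i <- j + 1L
  }
  cm <- confusion_matrix(pred, actual)
  reports <- lapply(spect_classes(), function(cl) class_report(cm, cl))
  names(reports) <- spect_classes()
  macro <- vapply(c("recall", "precision", "accuracy", "specificity", "f1"),
                  function(m) {
                    v <- vapply(reports, `[[`, numeric(1), m)
                    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
                  }, numeric(1))
  structure(list(cm = cm, reports = reports, macro = as.list(macro), n = n),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: %d samples, macro precision %s>\n",
              x$n, fmt_pc(x$macro$precision)))
  print(x$cm)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits a machine-readable JSON report and a CSV metric table with one
#' row per metric (Recall, Precision, Accuracy, Specificity, F1 score)
#' and one column per class, values as percentages rounded half-even to
#' 2 decimals. Undefined metrics appear as JSON nulls / empty CSV cells.
#'
#' @param results An `eval_result` from [evaluate_model()].
#' @param out_dir Output directory (created if missing); writes
#'   `report.json` and `metrics.csv`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metric_names <- c(Recall = "recall", Precision = "precision",
                    Accuracy = "accuracy", Specificity = "specificity",
                    `F1 score` = "f1")
  tab <- sapply(spect_classes(), function(cl) {
    vapply(metric_names, function(m) {
      v <- results$reports[[cl]][[m]]
      if (is.na(v)) NA_real_ else round(100 * v, 2)
    }, numeric(1))
  })
  rownames(tab) <- names(metric_names)
  df <- data.frame(Metric = rownames(tab), tab, check.names = FALSE,
                   row.names = NULL)
  csv_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")

  json_path <- file.path(out_dir, "report.json")
  payload <- list(
    n = results$n,
    confusion_matrix = list(
      convention = "columns = actual class, rows = predicted class",
      classes = spect_classes(),
      counts = unname(apply(results$cm, 1L, as.integer, simplify = FALSE))),
    per_class = lapply(results$reports, function(r) {
      list(TP = r$TP, TN = r$TN, FP = r$FP, FN = r$FN,
           recall_pct = if (is.na(r$recall)) NULL else round(100 * r$recall, 2),
           precision_pct = if (is.na(r$precision)) NULL else round(100 * r$precision, 2),
           accuracy_pct = if (is.na(r$accuracy)) NULL else round(100 * r$accuracy, 2),
           specificity_pct = if (is.na(r$specificity)) NULL else round(100 * r$specificity, 2),
           f1_pct = if (is.na(r$f1)) NULL else round(100 * r$f1, 2))
    }),
    macro = lapply(results$macro, function(v)
      if (is.na(v)) NULL else round(100 * v, 2)))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(json = json_path, csv = csv_path))
}
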