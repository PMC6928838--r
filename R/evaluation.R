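#' Confusion matrix for multiclass single-label predictions
#'
#' Builds the `l x l` count table with rows indexed by true class and
#' columns by predicted class, in the given class order. The derived
#' per-class binary quantities are available via [cm_components()]:
#' `tp_i` (diagonal), `fn_i` (row sum minus diagonal), `fp_i` (column sum
#' minus diagonal) and `tn_i` (everything else), which satisfy
#' `tp_i + fn_i + fp_i + tn_i = total` for every class.
#'
#' @param true,predicted Equal-length vectors of class codes.
#' @param class_order Class codes fixing row/column order; defaults to the
#'   eight terrain classes.
#' @return An integer matrix of class `confusion_matrix`.
#' @examples
#' cm <- confusion_matrix(c("H", "H", "D"), c("H", "D", "D"),
#'                        class_order = c("H", "D"))
#' cm
#' @export
confusion_matrix <- function(true, predicted, class_order = class_codes()) {
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length", call. = FALSE)
  }
  bad <- !c(true, predicted) %in% class_order
  if (any(bad)) {
    stop("codes outside class_order: ",
         paste(unique(c(true, predicted)[bad]), collapse = ", "),
         call. = FALSE)
  }
  tt <- table(factor(true, levels = class_order),
              factor(predicted, levels = class_order))
  m <- matrix(as.integer(tt), length(class_order), length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @rdname confusion_matrix
#' @param cm A `confusion_matrix` (or plain count matrix).
#' @export
cm_components <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn, total = total)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted), n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

.check_nonempty_cm <- function(cm) {
  if (sum(cm) == 0) {
    stop("metric undefined on an empty confusion matrix", call. = FALSE)
  }
}

#' Overall (trace/total) accuracy
#'
#' Fraction of correctly classified items: the matrix trace over the total
#' count. For single-label multiclass data this equals both micro-averaged
#' precision and micro-averaged recall.
#'
#' @param cm A `confusion_matrix`.
#' @return A value in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  .check_nonempty_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Macro-averaged per-class binary accuracy
#'
#' Reduces the multiclass matrix to `l` one-vs-rest binary problems and
#' averages their binary accuracies:
#' `(1/l) * sum_i (tp_i + tn_i) / (tp_i + fn_i + fp_i + tn_i)`.
#' For `l > 2` this is *not* the same as [overall_accuracy()] (each off-
#' diagonal error counts as a true negative for the l-2 uninvolved
#' classes); the two coincide for binary problems and for diagonal
#' matrices.
#'
#' @param cm A `confusion_matrix`.
#' @return A value in `[0, 1]`.
#' @export
macro_accuracy <- function(cm) {
  .check_nonempty_cm(cm)
  p <- cm_components(cm)
  mean((p$tp + p$tn) / p$total)
}

#' Micro-averaged precision, recall and F1
#'
#' Pools true/false positives and negatives over all classes before
#' computing the metrics: precision `= sum(tp) / sum(tp + fp)`, recall
#' `= sum(tp) / sum(tp + fn)`, and F1 their harmonic mean. For single-label
#' multiclass data `sum(fp) = sum(fn)` (every error is one false positive
#' and one false negative), so micro precision, micro recall and overall
#' accuracy are identical.
#'
#' @param cm A `confusion_matrix`.
#' @return A list with `precision`, `recall` and `f1`.
#' @export
micro_metrics <- function(cm) {
  .check_nonempty_cm(cm)
  p <- cm_components(cm)
  denom_p <- sum(p$tp) + sum(p$fp)
  denom_r <- sum(p$tp) + sum(p$fn)
  if (denom_p == 0) stop("micro precision undefined: no predicted positives",
                         call. = FALSE)
  if (denom_r == 0) stop("micro recall undefined: no true positives or false negatives",
                         call. = FALSE)
  precision <- sum(p$tp) / denom_p
  recall <- sum(p$tp) / denom_r
  if (precision + recall == 0) {
    stop("F1 undefined: precision + recall is zero", call. = FALSE)
  }
  list(precision = precision, recall = recall,
       f1 = 2 * precision * recall / (precision + recall))
}

#' Row-normalized confusion matrix
#'
#' Divides each nonzero row by its row sum (zero rows stay zero). The
#' diagonal entries of the result are the per-class recalls.
#'
#' @param cm A `confusion_matrix`.
#' @return A row-stochastic numeric matrix.
#' @export
normalize_rows <- function(cm) {
  rs <- rowSums(cm)
  out <- unclass(cm) * 1.0
  nz <- rs > 0
  out[nz, ] <- out[nz, , drop = FALSE] / rs[nz]
  out
}

#' Full metrics report
#'
#' Computes the complete evaluation suite for one confusion matrix:
#' overall (trace/total) accuracy, the macro-averaged per-class binary
#' accuracy, micro precision/recall/F1, and the per-class normalized
#' diagonal (per-class recalls). Both accuracy readings are reported side
#' by side because they answer different questions and diverge for more
#' than two classes.
#'
#' @param cm A `confusion_matrix`.
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(cm) {
  mm <- micro_metrics(cm)
  structure(list(
    overall_accuracy = overall_accuracy(cm),
    macro_accuracy = macro_accuracy(cm),
    micro_precision = mm$precision,
    micro_recall = mm$recall,
    f1_micro = mm$f1,
    per_class_recall = diag(normalize_rows(cm)),
    n = sum(cm)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics over %d tiles\n", x$n))
  cat(sprintf("  overall accuracy        %.4f\n", x$overall_accuracy))
  cat(sprintf("  macro binary accuracy   %.4f\n", x$macro_accuracy))
  cat(sprintf("  micro precision/recall  %.4f / %.4f\n",
              x$micro_precision, x$micro_recall))
  cat(sprintf("  micro F1                %.4f\n", x$f1_micro))
  cat("  per-class recall:\n")
  print(round(x$per_class_recall, 4))
  invisible(x)
}

#' Serialize evaluation artifacts
#'
#' `write_metrics_report()` writes the report as JSON;
#' `write_confusion_csv()` writes counts (or a normalized matrix) as CSV.
#'
#' @param report A `metrics_report`.
#' @param path Output file.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics_report
#' @param cm A confusion matrix or normalized matrix.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' Evaluate a classifier on a labeled manifest
#'
#' Convenience wrapper: predicts every tile, builds the confusion matrix
#' against the manifest labels and returns the metrics report alongside it.
#'
#' @param model A fitted `patch_cnn`.
#' @param manifest Labeled `patch_manifest`.
#' @param tiles Optional in-memory tiles aligned with the manifest.
#' @return A list with `confusion` and `metrics`.
#' @export
evaluate_classifier <- function(model, manifest, tiles = NULL) {
  pred <- predict(model, if (is.null(tiles)) manifest else tiles)
  cm <- confusion_matrix(manifest$class_code, pred,
                         class_order = model$class_order)
  list(confusion = cm, metrics = metrics_report(cm))
}
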