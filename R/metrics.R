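# Confusion-matrix criteria for imbalanced classification, regression
# metrics, and linear-model feature ranking.

METRIC_CRITERIA <- c("F1", "FPR", "TPR", "precision", "NPV", "FDR")

#' Six-criteria classification metrics from a confusion matrix
#'
#' Computes TP/FP/FN/TN and the six rates used throughout the pipeline:
#' F1, precision, TPR (recall), FPR, NPV and FDR (= 1 - precision).
#' Zero-denominator ratios are returned as `NA` and recorded in the
#' `undefined` field, except F1 which is defined as 0 when
#' precision + recall is 0 (the usual degenerate convention for
#' all-negative predictions on mixed labels).
#'
#' @param true_labels,predicted_labels equal-length binary 0/1 vectors.
#' @return a `metric_report`: list with counts, the six rates, and
#'   `undefined` (names of rates with empty denominators).
#' @export
classification_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) stop("empty input")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  assert_binary_labels(true_labels); assert_binary_labels(predicted_labels)
  tp <- sum(true_labels == 1L & predicted_labels == 1L)
  fp <- sum(true_labels == 0L & predicted_labels == 1L)
  fn <- sum(true_labels == 1L & predicted_labels == 0L)
  tn <- sum(true_labels == 0L & predicted_labels == 0L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  tpr <- safe_div(tp, tp + fn)
  fpr <- safe_div(fp, fp + tn)
  npv <- safe_div(tn, tn + fn)
  fdr <- if (is.na(precision)) NA_real_ else 1 - precision
  f1 <- if (is.na(precision) || is.na(tpr) || precision + tpr == 0) {
    0
  } else {
    2 * precision * tpr / (precision + tpr)
  }
  vals <- c(precision = precision, TPR = tpr, FPR = fpr, NPV = npv, FDR = fdr)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 F1 = f1, precision = precision, TPR = tpr,
                 FPR = fpr, NPV = npv, FDR = fdr,
                 undefined = names(vals)[is.na(vals)]),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> TP=%d FP=%d FN=%d TN=%d | F1=%.4f prec=%.4f TPR=%.4f FPR=%.4f NPV=%.4f FDR=%.4f\n",
              x$TP, x$FP, x$FN, x$TN, x$F1, x$precision, x$TPR, x$FPR,
              x$NPV, x$FDR))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(TP = x$TP, FP = x$FP, FN = x$FN, TN = x$TN,
             F1 = x$F1, precision = x$precision, TPR = x$TPR,
             FPR = x$FPR, NPV = x$NPV, FDR = x$FDR)
}

#' Regression metrics: MSE and R-squared
#'
#' `R2 = 1 - SS_res/SS_tot`. A constant truth vector leaves R-squared
#' undefined; it is returned as `NA` with a warning while MSE is still
#' reported.
#'
#' @param true_values,predicted_values equal-length numeric vectors
#'   (length >= 2).
#' @return list with `MSE` and `R2`.
#' @export
regression_metrics <- function(true_values, predicted_values) {
  if (length(true_values) != length(predicted_values))
    stop("vectors must have equal length")
  if (length(true_values) < 2L) stop("need at least 2 observations")
  mse <- mean((true_values - predicted_values)^2)
  ss_tot <- sum((true_values - mean(true_values))^2)
  if (ss_tot == 0) {
    warning("constant truth: R-squared undefined, returning NA")
    return(list(MSE = mse, R2 = NA_real_))
  }
  list(MSE = mse, R2 = 1 - sum((true_values - predicted_values)^2) / ss_tot)
}

#' Rank features of a fitted linear classifier by coefficient magnitude
#'
#' Importance is the absolute value of the (standardised-scale) model
#' coefficient, in descending order; ties keep stable input order. The
#' ranking is only comparable across features when the model was fitted
#' on standardised features -- a warning is raised otherwise.
#'
#' @param model a fitted classifier handle from [train_classifier()].
#' @param feature_names optional names overriding those stored in the
#'   handle.
#' @return data.frame with columns `feature`, `importance`, `rank`,
#'   ordered by descending importance.
#' @export
rank_features <- function(model, feature_names = NULL) {
  stopifnot(inherits(model, "fitrank_classifier"))
  if (!isTRUE(model$standardize))
    warning("model was fitted on unstandardised features; ",
            "importances are not comparable across feature scales")
  beta <- model$coefficients
  feature_names <- feature_names %||% names(beta)
  stopifnot(length(feature_names) == length(beta))
  imp <- abs(unname(beta))
  ord <- order(-imp)  # stable: ties keep input order
  data.frame(feature = feature_names[ord], importance = imp[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
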