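# Evaluation: regression metrics, classification-by-regression with a
# neutral band, threshold scanning, and benchmarking of external ddG/dTm
# predictors supplied as CSV.

#' Regression metrics
#'
#' Pearson's r, mean squared error, Kendall's tau (tie-corrected tau-b) and
#' Spearman's rank correlation between observed and predicted values.
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 3).
#' @return List of class `gs_eval_report` with `pearson`, `mse`,
#'   `kendall_tau`, `spearman_rho` and `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 3L) {
    gs_error("gs_config_error", "need equal-length vectors of at least 3 values")
  }
  if (stats::sd(y_true) == 0) {
    gs_error("gs_degenerate_error", "y_true is constant; correlations undefined")
  }
  structure(list(
    pearson = stats::cor(y_true, y_pred),
    mse = mean((y_true - y_pred)^2),
    kendall_tau = stats::cor(y_true, y_pred, method = "kendall"),
    spearman_rho = stats::cor(y_true, y_pred, method = "spearman"),
    n = length(y_true)), class = "gs_eval_report")
}

#' @export
print.gs_eval_report <- function(x, ...) {
  cat(sprintf("<gs_eval_report> n=%d pearson=%.3f mse=%.3f tau=%.3f rho=%.3f\n",
              x$n, x$pearson, x$mse, x$kendall_tau, x$spearman_rho))
  invisible(x)
}

#' Classify continuous stability values with a neutral band
#'
#' Values below `lo` are destabilizing, above `hi` stabilizing, and values
#' inside the closed band (boundaries included) are neutral.
#'
#' @param values Numeric vector (dTm or ddG scale).
#' @param lo,hi Band limits, `lo <= 0 <= hi`.
#' @return Factor with levels destabilizing, neutral, stabilizing.
#' @export
classify_by_regression <- function(values, lo = -0.1, hi = 0.1) {
  if (!(lo <= 0 && 0 <= hi)) gs_error("gs_config_error", "need lo <= 0 <= hi")
  out <- ifelse(values < lo, "destabilizing",
                ifelse(values > hi, "stabilizing", "neutral"))
  factor(out, levels = c("destabilizing", "neutral", "stabilizing"))
}

#' Binary stabilizing/destabilizing labels
#'
#' Sign rule used for the stabilizing-mutation recovery test: positive
#' values map to 1 (stabilizing), negative values to 0; exact zero maps
#' to 0.
#'
#' @param values Numeric vector.
#' @return Integer vector of 0/1 labels.
#' @export
binary_stabilizing <- function(values) {
  as.integer(values > 0)
}

#' Classification metrics: accuracy, multiclass MCC, weighted F1
#'
#' MCC uses the generalised multiclass definition (Gorodkin); weighted F1
#' is the support-weighted mean of per-class F1 scores. A degenerate MCC
#' denominator (single observed class) yields 0 with a warning.
#'
#' @param true_labels,pred_labels Vectors/factors over a shared label set.
#' @return Named numeric vector `c(accuracy =, mcc =, weighted_f1 =)`.
#' @export
classification_metrics <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    gs_error("gs_config_error", "label vectors must have equal length")
  }
  lev <- union(levels(factor(true_labels)), levels(factor(pred_labels)))
  t <- factor(true_labels, levels = lev)
  p <- factor(pred_labels, levels = lev)
  cm <- table(t, p)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n

  # generalised (Gorodkin) multiclass MCC from the confusion matrix
  tsum <- rowSums(cm)    # true class totals
  psum <- colSums(cm)    # predicted class totals
  num <- sum(diag(cm)) * n - sum(tsum * psum)
  den <- sqrt(n^2 - sum(psum^2)) * sqrt(n^2 - sum(tsum^2))
  if (den == 0) {
    gs_warn("gs_degenerate_warning", "single-class labels: MCC undefined, returning 0")
    mcc <- 0
  } else {
    mcc <- num / den
  }

  f1 <- vapply(lev, function(l) {
    tp <- cm[l, l]; fp <- sum(cm[, l]) - tp; fn <- sum(cm[l, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- tsum / n
  c(accuracy = acc, mcc = mcc, weighted_f1 = sum(support * f1))
}

#' Scan symmetric neutral bands
#'
#' Evaluates the three-class classification at every symmetric band
#' (-t, t), t = `start`, `start + step`, ..., `max`. The truth values are
#' classified with the band under scan while predictions are classified
#' with `pred_band` (each method keeps its own thresholds; defaults to the
#' scanned band when `NULL`).
#'
#' @param y_true Experimental values (dTm scale).
#' @param y_pred Predicted values.
#' @param start,step,max Scan grid parameters.
#' @param pred_band Optional fixed `c(lo, hi)` band for the predictions.
#' @return List: `table` (band_lo, band_hi, accuracy, mcc, weighted_f1 per
#'   scanned band) and `best` (the MCC-argmax row).
#' @export
threshold_scan <- function(y_true, y_pred, start = 0.1, step = 0.05, max = 3.0,
                           pred_band = NULL) {
  if (step <= 0 || start > max) gs_error("gs_config_error", "need step > 0 and start <= max")
  ts <- seq(start, max, by = step)
  rows <- lapply(ts, function(t) {
    truth <- classify_by_regression(y_true, -t, t)
    pb <- if (is.null(pred_band)) c(-t, t) else pred_band
    pred <- classify_by_regression(y_pred, pb[1], pb[2])
    m <- suppressWarnings(classification_metrics(truth, pred))
    data.frame(band_lo = -t, band_hi = t, accuracy = m["accuracy"],
               mcc = m["mcc"], weighted_f1 = m["weighted_f1"], row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, best = tab[which.max(tab$mcc), , drop = FALSE])
}

#' Benchmark external predictors against experimental labels
#'
#' Each method's predictions (CSV columns `key`, `value`) are classified
#' with that method's own neutral band while the experimental dTm values
#' use `truth_band`; the three-class metrics are reported per method.
#'
#' @param truth Data frame with `key` and `dTm` columns.
#' @param methods Named list; each element a list with `predictions` (data
#'   frame `key`, `value`) and `band` (`c(lo, hi)`).
#' @param truth_band Band applied to the experimental values.
#' @return Data frame: method, thresholds, accuracy, mcc, weighted_f1.
#' @export
benchmark_predictors <- function(truth, methods, truth_band = c(-0.1, 0.1)) {
  rows <- lapply(names(methods), function(nm) {
    m <- methods[[nm]]
    merged <- merge(truth, m$predictions, by = "key")
    if (nrow(merged) == 0L) gs_error("gs_data_error",
                                     sprintf("no overlapping keys for method '%s'", nm))
    t_lab <- classify_by_regression(merged$dTm, truth_band[1], truth_band[2])
    p_lab <- classify_by_regression(merged$value, m$band[1], m$band[2])
    met <- suppressWarnings(classification_metrics(t_lab, p_lab))
    data.frame(method = nm, band_lo = m$band[1], band_hi = m$band[2],
               accuracy = met["accuracy"], mcc = met["mcc"],
               weighted_f1 = met["weighted_f1"], n = nrow(merged),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
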