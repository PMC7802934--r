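# Agreement metrics, ROC machinery and correlation/AUC comparison tests.

#' Pearson correlation between experimental and predicted values
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-constant).
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop_mutstab("length mismatch", "mutstab_shape_error")
  if (length(x) < 3)
    stop_mutstab("need at least 3 observations", "mutstab_value_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_mutstab("correlation undefined for constant input",
                 "mutstab_value_error")
  stats::cor(x, y)
}

#' Root-mean-square error
#'
#' @param predicted,experimental Equal-length numeric vectors (kcal/mol).
#' @return RMSE (kcal/mol).
#' @export
rmse <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop_mutstab("length mismatch", "mutstab_shape_error")
  sqrt(mean((predicted - experimental)^2))
}

#' Regression slope of predicted on experimental values
#'
#' @param predicted,experimental Equal-length numeric vectors.
#' @return Least-squares slope.
#' @export
fit_slope <- function(predicted, experimental) {
  unname(stats::coef(stats::lm(predicted ~ experimental))[2])
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the denominator is zero (but the confusion matrix
#' is non-empty) the value is 0 by convention.
#'
#' @param tp,tn,fp,fn Non-negative integer confusion-matrix counts.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_mutstab("counts must be non-negative integers",
                 "mutstab_value_error")
  if (sum(counts) == 0)
    stop_mutstab("empty confusion matrix", "mutstab_value_error")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC analysis with maximum-MCC threshold search
#'
#' Sweeps classification thresholds over the unique scores (predicting
#' positive when score >= threshold), computing TPR = TP/(TP+FN) and
#' FPR = FP/(FP+TN) at each, the area under the ROC curve by the
#' trapezoid rule, and the maximal MCC over the same sweep.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or 0/1) true labels; both classes required.
#' @return Object of class `ddg_roc`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `max_mcc`, `max_mcc_threshold`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop_mutstab("length mismatch", "mutstab_shape_error")
  if (!any(labels) || all(labels))
    stop_mutstab("both classes must be present", "mutstab_class_error")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(labels)
  nn <- sum(!labels)
  tpr <- fpr <- mccs <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- scores >= thr[i]
    tp <- sum(pos & labels); fp <- sum(pos & !labels)
    fn <- np - tp; tn <- nn - fp
    tpr[i] <- tp / np
    fpr[i] <- fp / nn
    mccs[i] <- mcc(tp, tn, fp, fn)
  }
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                               utils::tail(tpr[ord], -1)) / 2)
  best <- which.max(mccs)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 max_mcc = mccs[best], max_mcc_threshold = thr[best]),
            class = "ddg_roc")
}

#' @export
print.ddg_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, max MCC = %.3f at threshold %.3g\n",
              x$auc, x$max_mcc, x$max_mcc_threshold))
  invisible(x)
}

#' Label highly destabilizing / stabilizing mutations
#'
#' Highly destabilizing: `ddg_exp >= 1.0` kcal/mol (inclusive); highly
#' stabilizing: `ddg_exp <= -1.0` kcal/mol (inclusive).
#'
#' @param ddg_exp Experimental ddG values.
#' @return List of two logical vectors, `highly_destabilizing` and
#'   `highly_stabilizing`.
#' @export
label_extremes <- function(ddg_exp) {
  if (any(!is.finite(ddg_exp)))
    stop_mutstab("non-finite ddG", "mutstab_value_error")
  list(highly_destabilizing = ddg_exp >= 1.0,
       highly_stabilizing = ddg_exp <= -1.0)
}

#' Anti-symmetry audit of paired forward/reverse predictions
#'
#' For a perfectly anti-symmetric predictor the forward and reverse
#' predictions of each pair sum to zero: the correlation `R_FR` is -1
#' and the mean pairwise sum (bias) is 0.
#'
#' @param pred_forward,pred_reverse Paired prediction vectors.
#' @return List with `R_FR` and `bias` (kcal/mol).
#' @export
antisymmetry_audit <- function(pred_forward, pred_reverse) {
  if (length(pred_forward) != length(pred_reverse))
    stop_mutstab("paired arrays must have equal length",
                 "mutstab_shape_error")
  list(R_FR = pearson_r(pred_forward, pred_reverse),
       bias = mean(pred_forward + pred_reverse))
}

#' Compare two correlations from independent groups (Fisher z)
#'
#' Two-sided test of equality of two Pearson correlations measured on
#' independent samples, via the Fisher z-transform.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return List with `z` and `p_value`.
#' @export
compare_correlations_independent <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_mutstab("correlations must satisfy |r| < 1",
                 "mutstab_value_error")
  if (n1 < 4 || n2 < 4)
    stop_mutstab("need n >= 4 in both groups", "mutstab_value_error")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors evaluated on the same labels,
#' using DeLong's covariance estimator for paired ROC curves.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Logical (or 0/1) labels; both classes required.
#' @return List with `auc_a`, `auc_b` and `p_value` (two-sided).
#' @export
delong_auc_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop_mutstab("both classes must be present", "mutstab_class_error")
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_mutstab("length mismatch", "mutstab_shape_error")
  ra <- pROC::roc(response = labels, predictor = scores_a,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = labels, predictor = scores_b,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  if (identical(scores_a, scores_b))
    return(list(auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)), p_value = 1))
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- tt$p.value
  if (is.na(p)) p <- 1  # zero-variance difference
  list(auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)),
       p_value = p)
}

#' Evaluate predictions against experiment
#'
#' Computes R, RMSE, slope and n, optionally per stratum (e.g.
#' destabilizing/stabilizing, forward/reverse, COR/SUR).
#'
#' @param predicted,experimental Equal-length numeric vectors.
#' @param strata Optional named list of factors/character vectors of the
#'   same length; a breakdown is reported for each.
#' @return List of class `ddg_evaluation` with `R`, `RMSE`, `slope`,
#'   `n`, and `strata` (nested breakdowns).
#' @export
evaluate_predictions <- function(predicted, experimental, strata = NULL) {
  out <- list(R = pearson_r(predicted, experimental),
              RMSE = rmse(predicted, experimental),
              slope = fit_slope(predicted, experimental),
              n = length(predicted))
  if (!is.null(strata)) {
    out$strata <- lapply(strata, function(s) {
      lapply(split(seq_along(s), s), function(i) {
        if (length(i) >= 3 && stats::sd(predicted[i]) > 0 &&
            stats::sd(experimental[i]) > 0)
          list(R = pearson_r(predicted[i], experimental[i]),
               RMSE = rmse(predicted[i], experimental[i]),
               n = length(i))
        else list(R = NA_real_, RMSE = rmse(predicted[i], experimental[i]),
                  n = length(i))
      })
    })
  }
  class(out) <- "ddg_evaluation"
  out
}

#' @export
print.ddg_evaluation <- function(x, ...) {
  cat(sprintf("n = %d: R = %.3f, RMSE = %.3f kcal/mol, slope = %.3f\n",
              x$n, x$R, x$RMSE, x$slope))
  invisible(x)
}
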