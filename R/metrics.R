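# Rare-outcome evaluation protocol: discrimination, precision-recall,
# probability accuracy, threshold metrics, LOWESS calibration, percentile
# bootstrap intervals and paired bootstrap model comparison.

#' Construct / validate a prediction set
#'
#' @param patient_ids Character ids.
#' @param labels Observed outcomes in \{0, 1\}.
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @return A data.frame with columns `patient_id`, `label`, `probability`.
#' @export
prediction_set <- function(patient_ids, labels, probabilities) {
  stopifnot(length(patient_ids) == length(labels),
            length(labels) == length(probabilities),
            all(labels %in% c(0, 1)),
            all(probabilities >= 0 & probabilities <= 1))
  data.frame(patient_id = as.character(patient_ids),
             label = as.integer(labels),
             probability = as.numeric(probabilities),
             stringsAsFactors = FALSE)
}

check_pred <- function(pred) {
  stopifnot(is.data.frame(pred),
            all(c("label", "probability") %in% names(pred)))
  pred
}

auroc_values <- function(labels, probs) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_config("auroc: both classes must be present")
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney pair statistic: the probability that a randomly chosen
#' case scores above a randomly chosen control, ties counting one half.
#'
#' @param pred A prediction set (see [prediction_set()]).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(pred) {
  pred <- check_pred(pred)
  auroc_values(pred$label, pred$probability)
}

auprc_values <- function(labels, probs) {
  if (sum(labels == 1) == 0) stop_config("auprc: no positive labels")
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]
  p <- probs[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate at descending unique score thresholds (step interpolation:
  # average precision, never trapezoidal PR interpolation)
  last <- which(!duplicated(p, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / sum(labels == 1)
  sum(diff(c(0, recall)) * precision)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision summation over descending unique score thresholds:
#' `sum (R_i - R_{i-1}) * P_i`. The step-interpolation estimator is used
#' deliberately; trapezoidal PR interpolation is known to over-estimate.
#' The chance level equals the outcome prevalence.
#'
#' @param pred A prediction set.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(pred) {
  pred <- check_pred(pred)
  auprc_values(pred$label, pred$probability)
}

#' Brier score
#'
#' Mean squared error of the predicted probabilities, `mean((p - y)^2)`.
#' Reporting layers conventionally multiply by 100.
#'
#' @param pred A prediction set.
#' @return Brier score (raw scale).
#' @export
brier <- function(pred) {
  pred <- check_pred(pred)
  mean((pred$probability - pred$label)^2)
}

#' Threshold metrics at a probability cut-off
#'
#' Classifies positive when `probability >= cutoff` (inclusive) and reports
#' sensitivity, specificity, PPV and NPV from the confusion matrix. A rate
#' with an empty denominator is `NA` (undefined), never 0. The default
#' cut-off 0.004 matches an outcome prevalence of about 0.4%.
#'
#' @param pred A prediction set with both classes present.
#' @param cutoff Probability cut-off.
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`, plus the
#'   confusion counts `tp`, `fp`, `fn`, `tn` and `cutoff`.
#' @export
threshold_metrics <- function(pred, cutoff = 0.004) {
  pred <- check_pred(pred)
  pos <- pred$probability >= cutoff
  y <- pred$label == 1
  tp <- sum(pos & y); fp <- sum(pos & !y)
  fn <- sum(!pos & y); tn <- sum(!pos & !y)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
       tp = tp, fp = fp, fn = fn, tn = tn, cutoff = cutoff)
}

#' Number needed to test per detected case
#'
#' `round(1 / PPV)`: how many high-risk patients need additional diagnostic
#' testing to detect one case at the chosen cut-off.
#'
#' @param ppv Positive predictive value.
#' @return Integer count.
#' @export
number_needed_to_test <- function(ppv) {
  stopifnot(is.numeric(ppv), ppv > 0)
  round(1 / ppv)
}

#' LOWESS calibration curve
#'
#' Locally weighted scatterplot smoothing of the observed outcome on the
#' predicted probabilities, restricted to predictions at or below `trim`
#' (default 30%, where the mass of a rare outcome lives). The ideal curve is
#' the diagonal from (0, 0) to (1, 1).
#'
#' @param pred A prediction set with at least 20 points.
#' @param trim Upper probability bound for the fit.
#' @param lowess_frac Smoother span passed to [stats::lowess()].
#' @return data.frame with `predicted` (all `<= trim`) and `observed`.
#' @export
calibration_curve <- function(pred, trim = 0.30, lowess_frac = 2 / 3) {
  pred <- check_pred(pred)
  stopifnot(nrow(pred) >= 20L)
  keep <- pred$probability <= trim
  if (!any(keep)) stop_config("calibration_curve: all probabilities above trim")
  # iter = 0: robustness reweighting would treat the rare 1s of a binary
  # outcome as outliers and collapse the curve toward the majority class
  fit <- stats::lowess(pred$probability[keep], pred$label[keep],
                       f = lowess_frac, iter = 0)
  data.frame(predicted = fit$x, observed = fit$y)
}

resample_both_classes <- function(labels, n) {
  repeat {
    ix <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[ix])) > 1L) return(ix)
  }
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples (label, probability) pairs with replacement and takes the 2.5th
#' and 97.5th percentiles of the metric's bootstrap distribution. Resamples
#' containing a single class are redrawn, a necessary addition for rank
#' metrics under rare outcomes.
#'
#' @param pred A prediction set.
#' @param metric_fn Function of a prediction set returning a scalar.
#' @param n_boot Number of bootstrap samples.
#' @param seed Seed for resampling.
#' @param conf Confidence level.
#' @return Named list `point`, `lo`, `hi`, `n_boot`.
#' @export
bootstrap_ci <- function(pred, metric_fn, n_boot = 1000L, seed = 1L,
                         conf = 0.95) {
  pred <- check_pred(pred)
  point <- metric_fn(pred)
  n <- nrow(pred)
  with_seed(seed, {
    stat <- vapply(seq_len(n_boot), function(b) {
      ix <- resample_both_classes(pred$label, n)
      metric_fn(pred[ix, , drop = FALSE])
    }, numeric(1))
    qs <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE, na.rm = TRUE)
    list(point = point, lo = qs[1], hi = qs[2], n_boot = as.integer(n_boot))
  })
}

#' Paired bootstrap difference test between two models
#'
#' Both models are evaluated on identical patients; each resample draws the
#' same patients for both prediction sets, the metric difference (A - B) is
#' recorded, and significance holds when 0 lies outside the central 95%
#' percentile interval of the differences (two-sided p < 0.05).
#'
#' @param pred_a,pred_b Prediction sets over the same patients (matched by
#'   `patient_id`).
#' @param metric_fn Metric function of a prediction set.
#' @param n_boot Number of bootstrap samples.
#' @param seed Seed for resampling.
#' @return Named list `diff`, `lo`, `hi`, `significant`.
#' @export
bootstrap_diff_test <- function(pred_a, pred_b, metric_fn, n_boot = 1000L,
                                seed = 1L) {
  pred_a <- check_pred(pred_a)
  pred_b <- check_pred(pred_b)
  if (!identical(sort(pred_a$patient_id), sort(pred_b$patient_id))) {
    stop_config("bootstrap_diff_test: prediction sets cover different patients")
  }
  pred_b <- pred_b[match(pred_a$patient_id, pred_b$patient_id), , drop = FALSE]
  n <- nrow(pred_a)
  point <- metric_fn(pred_a) - metric_fn(pred_b)
  with_seed(seed, {
    diffs <- vapply(seq_len(n_boot), function(b) {
      ix <- resample_both_classes(pred_a$label, n)
      metric_fn(pred_a[ix, , drop = FALSE]) - metric_fn(pred_b[ix, , drop = FALSE])
    }, numeric(1))
    qs <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    list(diff = point, lo = qs[1], hi = qs[2],
         significant = !(0 >= qs[1] && 0 <= qs[2]))
  })
}

#' Full metric report for one model
#'
#' AUROC, AUPRC, Brier (raw and x100) and the threshold metrics at `cutoff`,
#' each with a percentile bootstrap confidence interval.
#'
#' @param pred A prediction set.
#' @param cutoff Probability cut-off for threshold metrics.
#' @param n_boot Bootstrap samples per interval.
#' @param seed Seed for resampling.
#' @return A list of class `"metric_report"`; each metric holds
#'   `point`, `lo`, `hi`.
#' @export
metric_report <- function(pred, cutoff = 0.004, n_boot = 1000L, seed = 1L) {
  pred <- check_pred(pred)
  thr <- function(field) function(p) threshold_metrics(p, cutoff)[[field]]
  rep_ <- list(
    auroc = bootstrap_ci(pred, auroc, n_boot, seed),
    auprc = bootstrap_ci(pred, auprc, n_boot, seed),
    brier = bootstrap_ci(pred, brier, n_boot, seed),
    sensitivity = bootstrap_ci(pred, thr("sensitivity"), n_boot, seed),
    specificity = bootstrap_ci(pred, thr("specificity"), n_boot, seed),
    ppv = bootstrap_ci(pred, thr("ppv"), n_boot, seed),
    npv = bootstrap_ci(pred, thr("npv"), n_boot, seed)
  )
  rep_$brier_x100 <- lapply(rep_$brier[c("point", "lo", "hi")],
                            function(v) 100 * v)
  rep_$cutoff <- cutoff
  rep_$n_boot <- as.integer(n_boot)
  rep_$n <- nrow(pred)
  class(rep_) <- "metric_report"
  rep_
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(m) sprintf("%.4f (%.4f, %.4f)", m$point, m$lo, m$hi)
  cat(sprintf("n=%d, cutoff=%.4g, %d bootstrap samples\n", x$n, x$cutoff,
              x$n_boot))
  cat("  AUROC:", fmt(x$auroc), "\n")
  cat("  AUPRC:", fmt(x$auprc), "\n")
  cat("  Brier (x100):", sprintf("%.3f (%.3f, %.3f)", x$brier_x100$point,
                                 x$brier_x100$lo, x$brier_x100$hi), "\n")
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("  %s: %s\n", m, fmt(x[[m]])))
  }
  invisible(x)
}
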