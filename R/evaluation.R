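# Diagnostic-performance evaluation with the non-responder as positive
# class: TP = NR predicted NR, TN = R predicted R.  All percentages are
# recomputable from the stored counts; display rounding is whole-percent,
# full precision is kept internally.

#' Confusion counts (non-responder positive)
#'
#' @param predictions Character vector (`"R"`/`"NR"`) or a
#'   [predict.response_model()] data.frame; when both carry `patient_id`s the
#'   records are matched by id.
#' @param truths Character vector of true labels, or data.frame with
#'   `patient_id` and `label`.
#' @return Object of class `confusion_counts`: `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_matrix <- function(predictions, truths) {
  if (is.data.frame(predictions)) {
    pid <- predictions$patient_id
    predictions <- predictions$predicted_label
  } else pid <- NULL
  if (is.data.frame(truths)) {
    if (is.null(pid)) qstop("data.frame truths require prediction patient_ids")
    m <- match(pid, truths$patient_id)
    if (anyNA(m)) qstop("unmatched patient ids between predictions and truths")
    truths <- truths$label[m]
  }
  if (length(predictions) != length(truths))
    qstop("predictions and truths differ in length")
  if (!all(c(predictions, truths) %in% c("R", "NR")))
    qstop("labels must be 'R' or 'NR'")
  structure(list(TP = sum(truths == "NR" & predictions == "NR"),
                 FN = sum(truths == "NR" & predictions == "R"),
                 TN = sum(truths == "R" & predictions == "R"),
                 FP = sum(truths == "R" & predictions == "NR")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> (NR positive) TP=%d FN=%d TN=%d FP=%d (n=%d)\n",
              x$TP, x$FN, x$TN, x$FP, x$TP + x$FN + x$TN + x$FP))
  invisible(x)
}

#' Exact Clopper–Pearson binomial confidence interval
#'
#' Beta-quantile form: `low = qbeta(alpha/2, s, n-s+1)` (0 when s = 0),
#' `high = qbeta(1-alpha/2, s+1, n-s)` (1 when s = n).
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param alpha Two-sided error level in (0, 1).
#' @return `c(low, high)` on the proportion scale.
#' @export
clopper_pearson_ci <- function(successes, n, alpha = 0.05) {
  if (n <= 0) qstop("n must be positive")
  if (successes < 0 || successes > n) qstop("successes must lie in 0..n")
  if (alpha <= 0 || alpha >= 1) qstop("alpha must lie in (0, 1)")
  low <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(low = low, high = high)
}

#' Standard logit confidence interval for a proportion
#'
#' `logit(p) +/- z * sqrt(1/num + 1/(den-num))`, back-transformed.  Boundary
#' proportions (0 or 1) are undefined on the logit scale and returned as
#' `NA` with a warning (convention: report the point estimate only).
#'
#' @param numerator,denominator Counts with `0 < numerator < denominator`
#'   for a defined interval.
#' @param alpha Two-sided error level.
#' @return `c(low, high)`.
#' @export
logit_ci <- function(numerator, denominator, alpha = 0.05) {
  if (denominator <= 0) qstop("denominator must be positive")
  if (alpha <= 0 || alpha >= 1) qstop("alpha must lie in (0, 1)")
  p <- numerator / denominator
  if (p <= 0 || p >= 1) {
    warning("proportion on the boundary: logit interval undefined", call. = FALSE)
    return(c(low = NA_real_, high = NA_real_))
  }
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(1 / numerator + 1 / (denominator - numerator))
  c(low = plogis(qlogis(p) - z * se), high = plogis(qlogis(p) + z * se))
}

metric_with_ci <- function(num, den, method = c("clopper_pearson", "logit"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (den == 0)
    return(structure(list(point = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, method = method,
                          defined = FALSE, numerator = num, denominator = den),
                     class = "metric_with_ci"))
  ci <- if (method == "clopper_pearson") clopper_pearson_ci(num, den, alpha)
  else suppressWarnings(logit_ci(num, den, alpha))
  structure(list(point = 100 * num / den, ci_low = 100 * ci[["low"]],
                 ci_high = 100 * ci[["high"]], method = method,
                 defined = TRUE, numerator = num, denominator = den),
            class = "metric_with_ci")
}

#' @export
print.metric_with_ci <- function(x, ...) {
  if (!x$defined) cat("undefined (zero denominator)\n")
  else cat(sprintf("%.0f%% (%.0f-%.0f%%) [%s]\n", x$point, x$ci_low,
                   x$ci_high, x$method))
  invisible(x)
}

#' Sensitivity, specificity, PPV, NPV and accuracy with CIs
#'
#' Non-responder is the positive class: sensitivity = TP/(TP+FN) is the
#' fraction of true non-responders called non-responders, specificity =
#' TN/(TN+FP) the fraction of responders called responders.  Sensitivity,
#' specificity and accuracy get exact Clopper–Pearson intervals; the
#' predictive values get standard logit intervals.  Zero-denominator metrics
#' are flagged undefined, never reported as 0.
#'
#' @param counts A [confusion_matrix()] result.
#' @param alpha CI error level.
#' @return Named list of `metric_with_ci` (`sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy`), class `classification_metrics`.
#' @export
classification_metrics <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    total <- TP + FN + TN + FP
    structure(list(
      sensitivity = metric_with_ci(TP, TP + FN, "clopper_pearson", alpha),
      specificity = metric_with_ci(TN, TN + FP, "clopper_pearson", alpha),
      ppv = metric_with_ci(TP, TP + FP, "logit", alpha),
      npv = metric_with_ci(TN, TN + FN, "logit", alpha),
      accuracy = metric_with_ci(TP + TN, total, "clopper_pearson", alpha),
      counts = counts),
      class = "classification_metrics")
  })
}

#' @export
print.classification_metrics <- function(x, ...) {
  print(x$counts)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    cat(sprintf("  %-12s ", m)); print(x[[m]])
  }
  invisible(x)
}

#' ROC curve and AUC from class scores
#'
#' AUC is the probability that a random non-responder scores above a random
#' responder, ties counting one half (the rank / concordance form); the ROC
#' is traced by sweeping a threshold over the observed scores.
#'
#' @param scores Numeric class scores (higher = more NR-like).
#' @param truths `"R"`/`"NR"` labels.
#' @return List: `auc`, `roc_points` (data.frame `fpr`, `tpr`, monotone
#'   nondecreasing).
#' @export
roc_auc <- function(scores, truths) {
  if (!all(truths %in% c("R", "NR"))) qstop("labels must be 'R' or 'NR'")
  pos <- truths == "NR"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) qstop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    c(fpr = sum(!pos & scores >= t) / n0, tpr = sum(pos & scores >= t) / n1)
  }, numeric(2)))
  list(auc = auc, roc_points = as.data.frame(pts))
}

#' Per-feature two-sample t-tests between response groups
#'
#' Unpaired t-test of each delta feature between responders and
#' non-responders; Welch (unequal variance) by default, Student's pooled as
#' option.  P-values are unadjusted.  Features with zero variance in both
#' groups are flagged undefined.
#'
#' @param deltas data.frame of delta features with a `label` column.
#' @param features Feature columns; defaults to the schema features present.
#' @param var_equal `FALSE` for Welch (default).
#' @return data.frame: `feature`, `t`, `df`, `p`, `mean_R`, `mean_NR`,
#'   `defined`.
#' @export
group_ttests <- function(deltas, features = NULL, var_equal = FALSE) {
  if (is.null(features))
    features <- intersect(qus_feature_names(), colnames(deltas))
  g <- deltas$label
  if (min(table(g)) < 2) qstop("need at least 2 records per group")
  rows <- lapply(features, function(f) {
    xr <- deltas[g == "R", f]; xn <- deltas[g == "NR", f]
    if (sd(xr) == 0 && sd(xn) == 0) {
      if (mean(xr) == mean(xn))
        return(data.frame(feature = f, t = 0, df = NA_real_, p = 1,
                          mean_R = mean(xr), mean_NR = mean(xn), defined = FALSE))
      return(data.frame(feature = f, t = NA_real_, df = NA_real_, p = NA_real_,
                        mean_R = mean(xr), mean_NR = mean(xn), defined = FALSE))
    }
    tt <- t.test(xn, xr, var.equal = var_equal)
    data.frame(feature = f, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_R = mean(xr), mean_NR = mean(xn), defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Full diagnostic-performance report
#'
#' Confusion counts, the five metrics with CIs, ROC/AUC from the class
#' scores, with an optional patient-exclusion list (exploratory re-analysis)
#' that re-triggers the whole report on the retained patients.
#'
#' @param predictions [predict.response_model()] data.frame (`patient_id`,
#'   `class_score`, `predicted_label`).
#' @param truths data.frame with `patient_id`, `label`.
#' @param exclude Patient ids to drop before evaluation.
#' @param alpha CI level.
#' @return Object of class `performance_report`.
#' @export
performance_report <- function(predictions, truths, exclude = NULL,
                               alpha = 0.05) {
  if (!is.null(exclude)) {
    predictions <- predictions[!predictions$patient_id %in% exclude, ]
    truths <- truths[!truths$patient_id %in% exclude, ]
  }
  counts <- confusion_matrix(predictions, truths)
  metrics <- classification_metrics(counts, alpha)
  truth_matched <- truths$label[match(predictions$patient_id, truths$patient_id)]
  roc <- roc_auc(predictions$class_score, truth_matched)
  structure(list(counts = counts, metrics = metrics, auc = roc$auc,
                 roc_points = roc$roc_points, n = length(truth_matched),
                 excluded = exclude),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> n = %d%s, AUC = %.2f\n", x$n,
              if (length(x$excluded)) sprintf(" (excluded %d)", length(x$excluded)) else "",
              x$auc))
  print(x$metrics)
  invisible(x)
}

#' Write a performance report to JSON (full precision) and ROC CSV
#'
#' @param report A [performance_report()].
#' @param path JSON output path.
#' @param roc_path Optional CSV path for the ROC points.
#' @export
write_performance_report <- function(report, path, roc_path = NULL) {
  m <- report$metrics
  as_list <- function(mm) list(point = mm$point, ci_low = mm$ci_low,
                               ci_high = mm$ci_high, method = mm$method,
                               defined = mm$defined)
  obj <- list(counts = unclass(report$counts),
              metrics = lapply(m[c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy")], as_list),
              auc = report$auc, n = report$n,
              excluded = as.list(report$excluded))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(roc_path))
    write.csv(report$roc_points, roc_path, row.names = FALSE)
  invisible(path)
}
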