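# Diagnostic metrics, exact/logit CIs, ROC/AUC, group t-tests.

test_that("confusion counts: validation outcome, perfect case, enumeration", {
  # 41/45 responders and 3/6 non-responders correct, n = 51
  truth <- c(rep("R", 45), rep("NR", 6))
  pred <- c(rep("R", 41), rep("NR", 4), rep("NR", 3), rep("R", 3))
  cm <- confusion_matrix(pred, truth)
  expect_identical(unclass(cm)[c("TP", "FN", "TN", "FP")],
                   list(TP = 3L, FN = 3L, TN = 41L, FP = 4L))

  cm0 <- confusion_matrix(rep(c("R", "NR"), 5), rep(c("R", "NR"), 5))
  expect_identical(cm0$FP + cm0$FN, 0L)

  set.seed(3)
  for (i in 1:25) {
    t_ <- sample(c("R", "NR"), 30, TRUE)
    p_ <- sample(c("R", "NR"), 30, TRUE)
    cm <- confusion_matrix(p_, t_)
    expect_identical(cm$TP, sum(t_ == "NR" & p_ == "NR"))
    expect_identical(cm$FP, sum(t_ == "R" & p_ == "NR"))
    expect_identical(cm$TP + cm$FN + cm$TN + cm$FP, 30L)
  }
  expect_error(confusion_matrix(c("R"), c("R", "NR")), "length")
})

test_that("metrics reproduce the printed validation row and round-trip", {
  cm <- structure(list(TP = 3L, FN = 3L, TN = 41L, FP = 4L),
                  class = "confusion_counts")
  m <- classification_metrics(cm)
  expect_identical(round(m$sensitivity$point), 50)
  expect_identical(round(m$specificity$point), 91)
  expect_identical(round(m$ppv$point), 43)
  expect_identical(round(m$npv$point), 93)
  expect_identical(round(m$accuracy$point), 86)
  # every reported % recomputable from the stored counts
  expect_equal(m$sensitivity$point, 100 * cm$TP / (cm$TP + cm$FN))
  expect_equal(m$accuracy$point, 100 * (cm$TP + cm$TN) / 51)

  perfect <- classification_metrics(confusion_matrix(rep(c("R", "NR"), 5),
                                                     rep(c("R", "NR"), 5)))
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_equal(perfect[[nm]]$point, 100)
})

test_that("metrics equal the formula oracle on 1000 random count tables", {
  set.seed(5)
  for (i in 1:1000) {
    v <- as.list(rmultinom(1, sample(4:200, 1), rep(0.25, 4))[, 1])
    names(v) <- c("TP", "FN", "TN", "FP")
    cm <- structure(v, class = "confusion_counts")
    m <- classification_metrics(cm)
    with(v, {
      if (TP + FN > 0) expect_equal(m$sensitivity$point, 100 * TP / (TP + FN))
      else expect_false(m$sensitivity$defined)
      if (TN + FP > 0) expect_equal(m$specificity$point, 100 * TN / (TN + FP))
      if (TP + FP > 0) expect_equal(m$ppv$point, 100 * TP / (TP + FP))
      else expect_false(m$ppv$defined)
      if (TN + FN > 0) expect_equal(m$npv$point, 100 * TN / (TN + FN))
      expect_equal(m$accuracy$point, 100 * (TP + TN) / (TP + FN + TN + FP))
    })
  }
})

test_that("Clopper-Pearson: boundaries exact, frozen beta-quantile values", {
  expect_identical(clopper_pearson_ci(0, 10)[["low"]], 0)
  expect_identical(clopper_pearson_ci(10, 10)[["high"]], 1)
  # frozen from the beta-quantile oracle: qbeta(.025, 3, 4), qbeta(.975, 4, 3)
  ci <- clopper_pearson_ci(3, 6, 0.05)
  expect_equal(ci[["low"]], 0.11812, tolerance = 1e-4)
  expect_equal(ci[["high"]], 0.88188, tolerance = 1e-4)
  expect_error(clopper_pearson_ci(1, 0), "positive")
  expect_error(clopper_pearson_ci(7, 6), "0..n")
})

test_that("logit CI: formula oracle, symmetry, nesting, boundary", {
  # oracle recomputed directly from the back-transformed formula
  ci <- logit_ci(41, 44, 0.05)
  p <- 41 / 44; se <- sqrt(1 / 41 + 1 / 3)
  expect_equal(ci[["low"]], plogis(qlogis(p) - 1.959964 * se), tolerance = 1e-6)
  expect_equal(ci[["high"]], plogis(qlogis(p) + 1.959964 * se), tolerance = 1e-6)
  expect_true(ci[["low"]] < 0.932 && ci[["high"]] > 0.932)

  big <- logit_ci(5000, 10000, 0.05)
  expect_equal(big[["low"]] + big[["high"]], 1, tolerance = 1e-6)

  w10 <- logit_ci(30, 50, 0.10); w05 <- logit_ci(30, 50, 0.05)
  w01 <- logit_ci(30, 50, 0.01)
  expect_true(w01[["low"]] < w05[["low"]] && w05[["low"]] < w10[["low"]])
  expect_true(w01[["high"]] > w05[["high"]] && w05[["high"]] > w10[["high"]])

  expect_warning(bad <- logit_ci(0, 10), "boundary")
  expect_true(all(is.na(bad)))
})

test_that("AUC: separation, binary identity, concordance oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c("R", "R", "R", "NR", "NR"))$auc, 1)
  set.seed(8)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    truths <- sample(c("R", "NR"), n, TRUE, prob = c(0.7, 0.3))
    if (length(unique(truths)) < 2) next
    scores <- sample(c(0, 1), n, TRUE)          # binary-valued scores
    r <- roc_auc(scores, truths)
    cm <- confusion_matrix(ifelse(scores > 0, "NR", "R"), truths)
    sens <- cm$TP / (cm$TP + cm$FN); spec <- cm$TN / (cm$TN + cm$FP)
    expect_equal(r$auc, (sens + spec) / 2, tolerance = 1e-12)
    expect_equal(r$auc, auc_oracle(scores, truths), tolerance = 1e-12)
    scores2 <- rnorm(n)
    r2 <- roc_auc(scores2, truths)
    expect_equal(r2$auc, auc_oracle(scores2, truths), tolerance = 1e-12)
    expect_true(all(diff(r2$roc_points$tpr) >= 0) &&
                  all(diff(r2$roc_points$fpr) >= 0))
    expect_true(r2$auc >= 0 && r2$auc <= 1)
  }
  expect_error(roc_auc(1:3, c("R", "R", "R")), "both classes")
})

test_that("group t-tests: identity, hand oracle, flags", {
  d <- data.frame(label = rep(c("R", "NR"), each = 4), check.names = FALSE)
  d$`MBF-mean` <- rep(c(1, 2, 3, 4), 2)     # identical groups
  tt <- group_ttests(d, "MBF-mean")
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)

  # Welch t recomputed by hand on printed vectors
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1)
  d2 <- data.frame(label = rep(c("NR", "R"), each = 6), check.names = FALSE)
  d2$`SS-COR` <- c(x, y)
  tt2 <- group_ttests(d2, "SS-COR")
  se <- sqrt(var(x) / 6 + var(y) / 6)
  expect_equal(tt2$t, (mean(x) - mean(y)) / se, tolerance = 1e-10)
  dfw <- se^4 / ((var(x) / 6)^2 / 5 + (var(y) / 6)^2 / 5)
  expect_equal(tt2$df, dfw, tolerance = 1e-8)
  expect_equal(tt2$p, 2 * pt(-abs(tt2$t), dfw), tolerance = 1e-10)

  d3 <- data.frame(label = rep(c("R", "NR"), each = 3), check.names = FALSE)
  d3$`SI-mean` <- c(1, 1, 1, 2, 2, 2)       # zero variance in both groups
  tt3 <- group_ttests(d3, "SI-mean")
  expect_false(tt3$defined)
  expect_true(is.na(tt3$p))
})

test_that("performance report: consistency and exclusion re-analysis", {
  set.seed(12)
  n <- 40
  truth <- data.frame(patient_id = sprintf("P%02d", 1:n),
                      label = sample(c("R", "NR"), n, TRUE, c(0.8, 0.2)))
  preds <- data.frame(patient_id = truth$patient_id,
                      class_score = rnorm(n) + (truth$label == "NR"),
                      stringsAsFactors = FALSE)
  preds$predicted_label <- ifelse(preds$class_score > 0, "NR", "R")
  rep1 <- performance_report(preds, truth)
  expect_equal(rep1$n, n)
  expect_equal(rep1$metrics$accuracy$point,
               100 * (rep1$counts$TP + rep1$counts$TN) / n)
  drop3 <- truth$patient_id[1:3]
  rep2 <- performance_report(preds, truth, exclude = drop3)
  expect_equal(rep2$n, n - 3)
  f <- tempfile(fileext = ".json")
  write_performance_report(rep1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$auc, rep1$auc, tolerance = 1e-12)
  expect_equal(back$counts$TP, rep1$counts$TP)
})
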