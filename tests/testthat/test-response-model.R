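# Feature selection and SVM-RBF response classification.

toy_records <- function(n = 40, sep = 4, seed = 1) {
  set.seed(seed)
  lab <- rep(c("R", "NR"), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2)
  X[lab == "NR", ] <- X[lab == "NR", ] + sep
  out <- cbind(data.frame(patient_id = sprintf("T%02d", 1:n), label = lab,
                          stringsAsFactors = FALSE), as.data.frame(X))
  colnames(out)[3:4] <- c("MBF-mean", "SS-COR")
  out
}

test_that("a separable toy problem trains to 100% accuracy", {
  rec <- toy_records()
  model <- train_svm(rec, c("MBF-mean", "SS-COR"), grid = list(C = 10, gamma = 0.5))
  pred <- predict(model, rec)
  expect_identical(pred$predicted_label, rec$label)
  expect_true(all(pred$class_score[rec$label == "NR"] > 0))
})

test_that("training is deterministic given records and seed", {
  rec <- toy_records(seed = 3)
  m1 <- train_svm(rec, c("MBF-mean", "SS-COR"), seed = 11)
  m2 <- train_svm(rec, c("MBF-mean", "SS-COR"), seed = 11)
  expect_identical(m1$svm$coef, m2$svm$coef)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
})

test_that("score sign fixes the label; negating the convention flips all", {
  rec <- toy_records(sep = 2, seed = 5)
  model <- train_svm(rec, c("MBF-mean", "SS-COR"), grid = list(C = 1, gamma = 0.5))
  pred <- predict(model, rec)
  expect_identical(pred$predicted_label, ifelse(pred$class_score > 0, "NR", "R"))
  flipped <- model
  flipped$svm$coef <- -flipped$svm$coef
  flipped$svm$b <- -flipped$svm$b
  pred2 <- predict(flipped, rec)
  strict <- pred$class_score != 0
  expect_true(all(pred$predicted_label[strict] != pred2$predicted_label[strict]))
})

test_that("selection contracts: k = 0, single class, zero variance, k range", {
  rec <- toy_records()
  expect_identical(sequential_feature_selection(rec, k = 0), character(0))
  single <- rec[rec$label == "R", ]
  expect_error(sequential_feature_selection(single, k = 1), "2 records per class")
  rec$flat <- 0
  expect_error(train_svm(rec, "flat"), "zero-variance.*flat")
  expect_error(sequential_feature_selection(rec, k = 99), "k must lie")
})

test_that("the planted informative feature is selected first", {
  hits <- vapply(1:5, function(s) {
    d <- simulate_delta_features(n_patients = 60, nonresponder_fraction = 0.25,
                                 informative = "SS-COR", effect = 1.5, seed = s)
    sel <- sequential_feature_selection(d, k = 1, seed = s)
    sel[1] == "SS-COR"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("no standardization leakage: scoring leaves the model unchanged", {
  rec <- toy_records(seed = 7)
  model <- train_svm(rec, c("MBF-mean", "SS-COR"), grid = list(C = 1, gamma = 0.5))
  centre_before <- model$centre; scale_before <- model$scale
  new <- toy_records(n = 20, sep = 1, seed = 99)
  invisible(predict(model, new))
  expect_identical(model$centre, centre_before)
  expect_identical(model$scale, scale_before)
  # refitting with validation rows appended changes the statistics: the
  # fitted centre really is a training-data quantity
  both <- rbind(rec, new)
  model2 <- train_svm(both, c("MBF-mean", "SS-COR"), grid = list(C = 1, gamma = 0.5))
  expect_false(identical(model2$centre, centre_before))
})

test_that("class score is monotone toward the NR centroid on a toy model", {
  rec <- toy_records(sep = 3, seed = 13)
  model <- train_svm(rec, c("MBF-mean", "SS-COR"), grid = list(C = 10, gamma = 0.2))
  X <- as.matrix(rec[, c("MBF-mean", "SS-COR")])
  centroid <- colMeans(X[rec$label == "NR", ])
  start <- X[which(rec$label == "R")[1], ]
  ts <- seq(0, 1, length.out = 25)
  path <- t(vapply(ts, function(t) start + t * (centroid - start), numeric(2)))
  nd <- as.data.frame(path)
  colnames(nd) <- c("MBF-mean", "SS-COR")
  scores <- predict(model, nd)$class_score
  expect_true(all(diff(scores) > -1e-8))
})

test_that("prediction guards and indeterminate zone work", {
  rec <- toy_records()
  model <- train_svm(rec, c("MBF-mean", "SS-COR"), grid = list(C = 1, gamma = 0.5))
  expect_error(predict(model, rec[, 1:3]), "missing feature")
  pred <- predict(model, rec, margin = 1e6)
  expect_true(all(pred$indeterminate))
})

test_that("model JSON round-trip preserves scores", {
  rec <- toy_records(seed = 17)
  model <- train_svm(rec, c("MBF-mean", "SS-COR"), grid = list(C = 1, gamma = 0.5))
  f <- tempfile(fileext = ".json")
  write_response_model(model, f)
  model2 <- read_response_model(f)
  expect_equal(predict(model2, rec)$class_score,
               predict(model, rec)$class_score, tolerance = 1e-9)
})
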