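# Delta-feature response classification: sequential forward feature
# selection and an SVM-RBF, with the non-responder as positive class.
#
# Sign convention (a single constant): positive class score => predicted
# non-responder, negative => responder.  The development description's text
# states this mapping; its figure caption states the opposite, and the text
# is taken as authoritative here.

NR_POSITIVE <- 1        # y = +1 for NR, -1 for R

label_to_y <- function(label) {
  if (!all(label %in% c("R", "NR"))) qstop("labels must be 'R' or 'NR'")
  ifelse(label == "NR", NR_POSITIVE, -NR_POSITIVE)
}

records_matrix <- function(records, features) {
  missing <- setdiff(features, colnames(records))
  if (length(missing)) qstop("missing feature columns: ",
                             paste(missing, collapse = ", "))
  as.matrix(records[, features, drop = FALSE])
}

# stratified k-fold assignment, deterministic given seed
make_folds <- function(y, k = 5, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

balanced_accuracy <- function(truth, predicted) {
  sens <- mean(predicted[truth == 1] == 1)
  spec <- mean(predicted[truth == -1] == -1)
  (sens + spec) / 2
}

# Cross-validated balanced accuracy of an SVM on given columns.
# Standardization is refit inside every training fold (no leakage).
cv_score <- function(X, y, folds, C = 1, gamma = NULL, class_weights = NULL) {
  pred <- integer(length(y))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    if (length(unique(y[tr])) < 2) { pred[!tr] <- 1; next }
    fit <- svm_rbf_fit(Xtr, y[tr], C = C, gamma = gamma,
                       class_weights = class_weights)
    s <- svm_rbf_decision(fit, Xte)
    pred[!tr] <- ifelse(s > 0, 1L, -1L)
  }
  balanced_accuracy(y, pred)
}

default_class_weights <- function(y) {
  n <- length(y)
  c(`-1` = n / (2 * sum(y == -1)), `1` = n / (2 * sum(y == 1)))
}

#' Sequential forward feature selection
#'
#' Greedy forward selection over the 31 delta features, adding at each step
#' the feature that maximizes stratified cross-validated balanced accuracy of
#' the SVM-RBF (default hyperparameters during the search); ties break to the
#' earlier feature in schema order.  Deterministic given the records and fold
#' seed.
#'
#' @param records data.frame with a `label` column (`"R"`/`"NR"`) and feature
#'   columns.
#' @param k Number of features to select (0..number available).
#' @param features Candidate pool; defaults to all 31 schema features present.
#' @param n_folds,seed Cross-validation folds and fold seed.
#' @param C,gamma SVM hyperparameters used during scoring.
#' @param class_weights `TRUE` for inverse-prevalence weights.
#' @return Character vector of selected names (ordered), with attribute
#'   `scores` (CV balanced accuracy after each addition).
#' @export
sequential_feature_selection <- function(records, k = 3, features = NULL,
                                         n_folds = 5, seed = 1, C = 1,
                                         gamma = NULL, class_weights = TRUE) {
  if (is.null(features))
    features <- intersect(qus_feature_names(), colnames(records))
  if (k < 0 || k > length(features)) qstop("k must lie in 0..", length(features))
  if (k == 0) return(character(0))
  y <- label_to_y(records$label)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    qstop("need at least 2 records per class")
  X <- records_matrix(records, features)
  folds <- make_folds(y, n_folds, seed)
  cw <- if (isTRUE(class_weights)) default_class_weights(y) else NULL
  selected <- character(0); scores <- numeric(0)
  for (step in seq_len(k)) {
    cand <- setdiff(features, selected)
    sc <- vapply(cand, function(f)
      cv_score(X[, c(selected, f), drop = FALSE], y, folds, C, gamma, cw), 0)
    best <- cand[which.max(sc)]            # which.max: first max, schema order
    selected <- c(selected, best)
    scores <- c(scores, max(sc))
  }
  attr(selected, "scores") <- scores
  selected
}

#' Train the SVM-RBF response model
#'
#' Per-feature centring/scaling is fitted on the training records only, then
#' an SVM-RBF is fitted on the standardized selected features.  When a
#' hyperparameter grid is given, (C, gamma) are chosen by stratified k-fold
#' cross-validated balanced accuracy with a fixed fold seed.  Class imbalance
#' (the development cohort is ~4:1) is handled with inverse-prevalence class
#' weights by default.
#'
#' @param records Training data.frame (`label` + features).
#' @param selected_features Feature names to use.
#' @param grid List with numeric `C` and `gamma` candidates; scalars fix the
#'   hyperparameters.
#' @param n_folds,seed CV folds / fold seed.
#' @param class_weights `TRUE` for inverse-prevalence weighting.
#' @return Object of class `response_model`.
#' @export
train_svm <- function(records, selected_features,
                      grid = list(C = c(1, 10, 100), gamma = c(0.01, 0.1, 1)),
                      n_folds = 5, seed = 1, class_weights = TRUE) {
  y <- label_to_y(records$label)
  if (length(unique(y)) < 2) qstop("both classes must be present")
  X <- records_matrix(records, selected_features)
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0))
    qstop("zero-variance selected feature: ",
          paste(selected_features[sdv == 0], collapse = ", "))
  centre <- colMeans(X)
  Xs <- sweep(sweep(X, 2, centre), 2, sdv, "/")
  cw <- if (isTRUE(class_weights)) default_class_weights(y) else NULL

  combos <- expand.grid(C = grid$C, gamma = grid$gamma)
  if (nrow(combos) > 1) {
    folds <- make_folds(y, n_folds, seed)
    combos$score <- vapply(seq_len(nrow(combos)), function(r)
      cv_score(X, y, folds, combos$C[r], combos$gamma[r], cw), 0)
    best <- combos[which.max(combos$score), ]
  } else best <- cbind(combos, score = NA_real_)

  fit <- svm_rbf_fit(Xs, y, C = best$C, gamma = best$gamma, class_weights = cw)
  structure(list(selected_features = selected_features,
                 centre = centre, scale = sdv, svm = fit,
                 hyperparameters = list(C = best$C, gamma = best$gamma),
                 cv = if (nrow(combos) > 1) combos else NULL,
                 class_weights = cw, positive_class = "NR"),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("<response_model> SVM-RBF on", paste(x$selected_features, collapse = ", "),
      sprintf("\n  C = %g, gamma = %g, %d SVs; positive class = NR (score > 0)\n",
              x$hyperparameters$C, x$hyperparameters$gamma, x$svm$n_sv))
  invisible(x)
}

#' Predict treatment response for new patients
#'
#' Standardizes the selected delta features with the training statistics and
#' returns the signed class score (distance-to-hyperplane scale): score > 0
#' predicts non-responder, score <= 0 responder (ties at exactly 0 go to the
#' majority class, R).  Scores inside `(-margin, margin)` are flagged as the
#' indeterminate zone near the hyperplane.
#'
#' @param object A [train_svm()] model.
#' @param newdata data.frame of delta features (optionally with
#'   `patient_id`).
#' @param margin Half-width of the indeterminate zone on the score scale.
#' @param ... Unused.
#' @return data.frame: `patient_id`, `class_score`, `predicted_label`,
#'   `indeterminate`.
#' @export
predict.response_model <- function(object, newdata, margin = 0, ...) {
  X <- records_matrix(newdata, object$selected_features)
  Xs <- sweep(sweep(X, 2, object$centre), 2, object$scale, "/")
  score <- svm_rbf_decision(object$svm, Xs)
  if (any(!is.finite(score))) qstop("non-finite class score")
  data.frame(
    patient_id = if ("patient_id" %in% colnames(newdata)) newdata$patient_id
    else sprintf("P%03d", seq_len(nrow(X))),
    class_score = score,
    predicted_label = ifelse(score > 0, "NR", "R"),
    indeterminate = abs(score) < margin,
    stringsAsFactors = FALSE)
}

#' Serialize / restore a response model as JSON
#'
#' Plain-text archive of everything needed to score new patients: selected
#' features, standardization, kernel parameters and support data.
#'
#' @param model A `response_model`.
#' @param path Output (input) path.
#' @export
write_response_model <- function(model, path) {
  obj <- list(selected_features = model$selected_features,
              centre = as.list(model$centre), scale = as.list(model$scale),
              hyperparameters = model$hyperparameters,
              class_weights = as.list(model$class_weights),
              svm = list(X_sv = model$svm$X_sv, coef = model$svm$coef,
                         b = model$svm$b, gamma = model$svm$gamma,
                         C = model$svm$C),
              positive_class = "NR")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_response_model
#' @export
read_response_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X_sv <- obj$svm$X_sv
  if (!is.matrix(X_sv))
    X_sv <- matrix(unlist(X_sv), ncol = length(obj$selected_features),
                   byrow = TRUE)
  svm <- structure(list(X_sv = X_sv,
                        coef = obj$svm$coef, b = obj$svm$b,
                        gamma = obj$svm$gamma, C = obj$svm$C,
                        class_weights = unlist(obj$class_weights),
                        n_sv = length(obj$svm$coef)),
                   class = "svm_rbf")
  structure(list(selected_features = obj$selected_features,
                 centre = unlist(obj$centre), scale = unlist(obj$scale),
                 svm = svm, hyperparameters = obj$hyperparameters,
                 cv = NULL, class_weights = unlist(obj$class_weights),
                 positive_class = "NR"),
            class = "response_model")
}
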