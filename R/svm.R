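# Support vector machine with RBF kernel, solved exactly in the dual with
# quadprog.  Small-n classifier (the cohorts here are ~100 patients), written
# for determinism: identical inputs give identical support coefficients.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

# y in {-1, +1}; per-sample box constraints Cvec
svm_rbf_fit <- function(X, y, C = 1, gamma = NULL, class_weights = NULL,
                        ridge = 1e-8) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) qstop("y must be coded -1/+1")
  if (length(unique(y)) < 2) qstop("both classes must be present")
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)      # 'scale' on standardized data
  if (is.null(class_weights)) class_weights <- c(`-1` = 1, `1` = 1)
  Cvec <- C * unname(class_weights[as.character(y)])
  K <- rbf_kernel(X, X, gamma)
  D <- (y %*% t(y)) * K + diag(ridge, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), -Cvec)
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A, bvec = b0,
                            meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), Cvec)
  sv <- alpha > 1e-6 * max(alpha, 1)
  # bias from margin vectors (0 < alpha < C); fall back to all SVs
  margin <- sv & alpha < Cvec * (1 - 1e-6)
  use <- if (any(margin)) margin else sv
  f_no_b <- as.vector(K[, sv, drop = FALSE] %*% (alpha[sv] * y[sv]))
  b <- mean(y[use] - f_no_b[use])
  structure(list(X_sv = X[sv, , drop = FALSE], coef = alpha[sv] * y[sv],
                 b = b, gamma = gamma, C = C, class_weights = class_weights,
                 n_sv = sum(sv)),
            class = "svm_rbf")
}

svm_rbf_decision <- function(model, X) {
  X <- as.matrix(X)
  as.vector(rbf_kernel(X, model$X_sv, model$gamma) %*% model$coef + model$b)
}

#' @export
print.svm_rbf <- function(x, ...) {
  cat(sprintf("<svm_rbf> %d SVs, C = %g, gamma = %g\n", x$n_sv, x$C, x$gamma))
  invisible(x)
}
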