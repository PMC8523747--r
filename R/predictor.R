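#' Fitting specification for the elastic-net predictor
#'
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (0 = ridge,
#'   1 = lasso).  Default 0.5: an even mix, since "elastic net" without
#'   qualification implies both penalties.
#' @param nlambda Length of the automatic lambda grid.
#' @param lambda_min_ratio Smallest lambda as a fraction of the largest;
#'   defaults to 0.01 when `p >= n`, 1e-4 otherwise.
#' @param n_folds Inner cross-validation folds (stratified).
#' @param tol Coordinate-descent convergence tolerance.
#' @param maxit Maximum sweeps per fit.
#' @param standardize Standardize features to unit variance inside each
#'   training fold (no leakage).
#' @param cutoff Classification probability cutoff; ties (probability
#'   equal to the cutoff) classify positive.
#' @return Object of class `enet_spec`.
#' @export
enet_spec <- function(alpha = 0.5, nlambda = 50,
                      lambda_min_ratio = NULL, n_folds = 10,
                      tol = 1e-7, maxit = 10000, standardize = TRUE,
                      cutoff = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, nlambda >= 1, n_folds >= 2)
  structure(list(alpha = alpha, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = n_folds, tol = tol, maxit = maxit,
                 standardize = standardize, cutoff = cutoff),
            class = "enet_spec")
}

#' Automatic descending lambda grid
#'
#' `lambda_max` is the smallest lambda at which every coefficient is
#' zero, `max |X'(y - ybar)| / (n * max(alpha, 0.001))`; the grid is
#' log-spaced down to `lambda_max * lambda_min_ratio`.
#'
#' @param X Feature matrix (standardized if the fit will be).
#' @param y Binary 0/1 outcome.
#' @param alpha Mixing parameter.
#' @param nlambda Grid length.
#' @param lambda_min_ratio See [enet_spec()].
#' @return Decreasing numeric vector of lambdas.
#' @export
enet_lambda_grid <- function(X, y, alpha, nlambda = 50,
                             lambda_min_ratio = NULL) {
  n <- nrow(X)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (ncol(X) >= n) 0.01 else 1e-4
  lmax <- max(abs(crossprod(X, y - mean(y)))) / (n * max(alpha, 0.001))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio),
          length.out = nlambda))
}

standardize_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr,
       scale = scl)
}

# path fit on (optionally standardized) X; coefficients returned on the
# original feature scale
enet_path <- function(X, y, alpha, lambdas, spec) {
  std <- if (spec$standardize) standardize_train(X)
         else list(X = X, center = rep(0, ncol(X)),
                   scale = rep(1, ncol(X)))
  fit <- enet_logistic_path_cpp(std$X, y, alpha, lambdas, spec$tol,
                                spec$maxit, FALSE)
  if (any(fit$iterations >= spec$maxit))
    stop("elastic-net coordinate descent failed to converge; ",
         "iterations = ", max(fit$iterations),
         ", lambda range = [", min(lambdas), ", ", max(lambdas), "]")
  beta <- fit$beta / std$scale
  intercept <- fit$intercept - colSums(fit$beta * (std$center / std$scale))
  list(beta = beta, intercept = intercept, lambda = lambdas)
}

#' Fit an elastic-net logistic regression at one lambda
#'
#' Minimizes `-loglik/n + lambda * ((1 - alpha) ||beta||^2 / 2 +
#' alpha ||beta||_1)` (intercept unpenalized) by cyclic coordinate
#' descent on the IRLS quadratic approximation, warm-started along a
#' descending lambda path ending at the requested lambda.
#'
#' @param X Feature matrix (samples x features).
#' @param y Binary 0/1 (or logical) outcome.
#' @param alpha Mixing parameter.
#' @param lambda Penalty strength.
#' @param spec An [enet_spec()].
#' @return List with `beta` (original scale), `intercept`, `lambda`.
#' @export
enet_logistic_fit <- function(X, y, alpha = 0.5, lambda,
                              spec = enet_spec(alpha = alpha)) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  grid <- enet_lambda_grid(X, y, alpha, spec$nlambda)
  lambdas <- c(grid[grid > lambda], lambda)
  path <- enet_path(X, y, alpha, lambdas, spec)
  k <- length(lambdas)
  list(beta = path$beta[, k], intercept = path$intercept[k],
       lambda = lambda)
}

predict_enet <- function(beta, intercept, X) {
  eta <- intercept + as.numeric(X %*% beta)
  1 / (1 + exp(-eta))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Inner cross-validation over the lambda path
#'
#' Stratified k-fold CV of the full path; the deviance-minimizing
#' lambda (`lambda_min` rule) is selected.  Fold assignment is driven by
#' the caller's RNG state, so wrap in `set.seed()` for reproducibility.
#'
#' @inheritParams enet_logistic_fit
#' @param lambdas Descending lambda grid (default: automatic).
#' @return List with `lambda_min`, `cv_deviance` and the grid.
#' @export
cv_enet <- function(X, y, alpha = 0.5, lambdas = NULL,
                    spec = enet_spec(alpha = alpha)) {
  y <- as.numeric(y)
  if (is.null(lambdas))
    lambdas <- enet_lambda_grid(X, y, alpha, spec$nlambda,
                                spec$lambda_min_ratio)
  k <- min(spec$n_folds, min(table(y)))
  if (k < 2) stop("need at least two samples per class for inner CV")
  fold <- stratified_folds(y, k)
  dev <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold != f
    path <- enet_path(X[tr, , drop = FALSE], y[tr], alpha, lambdas, spec)
    for (l in seq_along(lambdas)) {
      p <- predict_enet(path$beta[, l], path$intercept[l],
                        X[!tr, , drop = FALSE])
      dev[f, l] <- binomial_deviance(y[!tr], p)
    }
  }
  mean_dev <- colMeans(dev)
  list(lambda_min = lambdas[which.min(mean_dev)],
       cv_deviance = mean_dev, lambda = lambdas)
}

#' Leave-one-out cross-validated mutation-status prediction
#'
#' For each sample, the optimal lambda is selected by stratified inner
#' cross-validation on the remaining `n - 1` samples (deviance
#' criterion), the model is refitted at that lambda, and the held-out
#' probability is recorded.  Features are standardized inside each
#' training set only.
#'
#' @param X Samples x features matrix (e.g. M values at candidate
#'   probes).
#' @param y Binary mutation status.
#' @param spec An [enet_spec()].
#' @return Object of class `prediction_report`: list with
#'   `probabilities` (out-of-fold, in input order), `predicted` labels,
#'   confusion counts, `sensitivity`, `specificity`, `lambda` per fold.
#' @export
loocv_predict <- function(X, y, spec = enet_spec()) {
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 10 || min(table(y)) < 3)
    stop("insufficient samples per class for leave-one-out CV")
  prob <- numeric(n)
  lam <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    cv <- cv_enet(Xtr, ytr, spec$alpha, spec = spec)
    fit <- enet_logistic_fit(Xtr, ytr, spec$alpha, cv$lambda_min, spec)
    prob[i] <- predict_enet(fit$beta, fit$intercept,
                            X[i, , drop = FALSE])
    lam[i] <- cv$lambda_min
  }
  rep <- confusion_metrics(prob, y, spec$cutoff)
  structure(c(list(probabilities = prob, lambda = lam), rep),
            class = "prediction_report")
}

#' Confusion-matrix metrics at a probability cutoff
#'
#' Probabilities at or above the cutoff classify positive (documented
#' tie rule).
#'
#' @param probabilities Predicted probabilities.
#' @param labels True binary labels.
#' @param cutoff Probability cutoff.
#' @return List with `predicted`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity` (`TP / (TP + FN)`) and `specificity`
#'   (`TN / (TN + FP)`).
#' @export
confusion_metrics <- function(probabilities, labels, cutoff = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(probabilities >= cutoff)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  list(predicted = pred, tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Association between predicted probability and clone size
#'
#' Linear regression of the out-of-fold predicted probability on VAF
#' among mutation carriers.
#'
#' @param probabilities Out-of-fold probabilities.
#' @param vaf VAF per sample.
#' @param carrier_mask Logical: which samples carry the mutation.
#' @return List with `slope`, `p_value` and `n`.
#' @export
prob_vs_clone_size <- function(probabilities, vaf, carrier_mask) {
  stopifnot(sum(carrier_mask) >= 3)
  fit <- lm(probabilities[carrier_mask] ~ vaf[carrier_mask])
  sm <- summary(fit)$coefficients
  list(slope = sm[2, 1], p_value = sm[2, 4], n = sum(carrier_mask))
}

# penalized objective and KKT residuals, used by the property tests
enet_objective <- function(X, y, intercept, beta, alpha, lambda) {
  eta <- intercept + as.numeric(X %*% beta)
  ll <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta
  mean(ll) + lambda * ((1 - alpha) * 0.5 * sum(beta^2) +
                       alpha * sum(abs(beta)))
}

enet_kkt_check <- function(X, y, intercept, beta, alpha, lambda) {
  p <- predict_enet(beta, intercept, X)
  grad <- -crossprod(X, y - p) / nrow(X) + lambda * (1 - alpha) * beta
  zero <- abs(beta) < 1e-10
  list(zero_ok = all(abs(grad[zero]) <= alpha * lambda + 1e-6),
       active_resid = max(c(0, abs(grad[!zero] +
                                   alpha * lambda * sign(beta[!zero])))))
}
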