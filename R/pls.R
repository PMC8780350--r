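#' Fit a partial least squares regression
#'
#' Iterative (NIPALS-style) PLS for a single response: both `X` and `y` are
#' autoscaled to zero mean and unit variance, then for each component
#' `i = 1..D` the unit weight vector `w_i = X_i' y_i / ||X_i' y_i||`
#' maximizes the covariance of the score `t_i = X_i w_i` with the response;
#' loadings `p_i = X_i' t_i / (t_i' t_i)` and coefficient
#' `q_i = y_i' t_i / (t_i' t_i)` follow, and `X`, `y` are deflated by the
#' component before the next iteration. Successive scores are mutually
#' orthogonal. With `D` equal to the number of (full-rank) predictors the
#' fit coincides with ordinary least squares.
#'
#' @param X Numeric matrix (N x P) of explanatory variables.
#' @param y Numeric response vector of length N.
#' @param D Number of latent components (default 2).
#' @return An object of class `pls_model` with weight matrix `W`, loadings
#'   `Pload`, coefficients `q`, standardization parameters, and the final
#'   residual matrices `E` and `f`.
#' @export
pls_fit <- function(X, y, D = 2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X); P <- ncol(X)
  if (length(y) != N) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (N <= D) stop("need more samples than components", call. = FALSE)
  if (D < 1 || D > P) stop("`D` must lie in [1, ncol(X)]", call. = FALSE)

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale <= 0)) {
    stop("constant explanatory column: cannot autoscale", call. = FALSE)
  }
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale <= 0) stop("constant response: cannot autoscale", call. = FALSE)

  Xi <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yi <- (y - y_center) / y_scale

  W <- matrix(0, P, D)
  Pload <- matrix(0, P, D)
  q <- numeric(D)
  for (i in seq_len(D)) {
    cov_xy <- drop(crossprod(Xi, yi))
    nrm <- sqrt(sum(cov_xy^2))
    if (nrm < 1e-12) {
      stop("degenerate component: response orthogonal to remaining X",
           call. = FALSE)
    }
    w <- cov_xy / nrm
    t_i <- drop(Xi %*% w)
    tt <- sum(t_i^2)
    p <- drop(crossprod(Xi, t_i)) / tt
    qi <- sum(yi * t_i) / tt
    Xi <- Xi - tcrossprod(t_i, p)
    yi <- yi - t_i * qi
    W[, i] <- w
    Pload[, i] <- p
    q[i] <- qi
  }

  structure(list(D = D, W = W, Pload = Pload, q = q,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 E = Xi, f = yi), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d predictor(s)\n",
              x$D, nrow(x$W)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Standardizes the query with the training parameters, projects it through
#' the stored weight/loading sequence (deflating the query alongside, exactly
#' as in fitting), accumulates `sum(t_i q_i)`, and de-standardizes.
#'
#' @param model A `pls_model` from [pls_fit()].
#' @param x Numeric vector of length P, or an N x P matrix of queries.
#' @return Predicted response (scalar or vector).
#' @export
pls_predict <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(model$W)) {
    stop("query dimension does not match the model", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  yhat <- numeric(nrow(X))
  for (i in seq_len(model$D)) {
    t_i <- drop(Xs %*% model$W[, i])
    yhat <- yhat + t_i * model$q[i]
    Xs <- Xs - tcrossprod(t_i, model$Pload[, i])
  }
  out <- yhat * model$y_scale + model$y_center
  if (is.matrix(x)) out else drop(out)
}

#' Cross-validated coefficient of determination for PLS
#'
#' For each candidate component count, K-fold cross-validation (seeded
#' shuffle) refits the PLS model and predicts the held-out fold; the score is
#' `r2_cv = 1 - sum((y_i - yhat_cv,i)^2) / sum((y_i - mean(y))^2)`. Used to
#' choose the component count; two components are the package default when
#' selection is skipped.
#'
#' @param X,y Data as in [pls_fit()].
#' @param D_candidates Integer vector of component counts to score.
#' @param folds Number of folds (>= 2, default 5).
#' @param seed Seed for the fold shuffle.
#' @return Named numeric vector of `r2_cv` per candidate.
#' @export
r2_cv <- function(X, y, D_candidates = 1:4, folds = 5, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("r2_cv undefined: constant response", call. = FALSE)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), N)))
  out <- vapply(D_candidates, function(D) {
    pred <- numeric(N)
    for (k in seq_len(folds)) {
      test <- fold_id == k
      fit <- pls_fit(X[!test, , drop = FALSE], y[!test], D = D)
      pred[test] <- pls_predict(fit, X[test, , drop = FALSE])
    }
    1 - sum((y - pred)^2) / sst
  }, numeric(1))
  stats::setNames(out, paste0("D", D_candidates))
}
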