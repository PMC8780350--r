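#' Fit a Gaussian process regressor
#'
#' Gaussian process regression with an RBF kernel contaminated by white
#' noise, on autoscaled inputs and response:
#' `k(x, x') = signal_var * exp(-||x - x'||^2 / (2 * rbf_scale^2)) +
#' noise_level * delta(x, x')`, with initial values `rbf_scale = 1`,
#' `signal_var = 1`, `noise_level = 1` on the standardized scale. When
#' `optimize` is on (the default) the three hyper-parameters are refined by
#' maximizing the log marginal likelihood from those initial values, with
#' each parameter bounded in `[1e-3, 1e3]`; with `optimize = FALSE` the
#' stated initial values are used as-is. The Gram matrix is factorized by a
#' Cholesky decomposition with jitter escalation (1e-10 up to 1e-6) on
#' failure.
#'
#' @param X Numeric matrix (N x P) of explanatory variables.
#' @param y Numeric response of length N.
#' @param optimize Refine hyper-parameters by marginal likelihood?
#' @param rbf_scale,signal_var,noise_level Initial kernel hyper-parameters.
#' @return An object of class `gpr_model`.
#' @export
gpr_fit <- function(X, y, optimize = TRUE,
                    rbf_scale = 1, signal_var = 1, noise_level = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  if (length(y) != N) stop("length(y) must equal nrow(X)", call. = FALSE)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  # constant columns (or a single sample) carry no kernel information
  x_scale[!is.finite(x_scale) | x_scale <= 0] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale <= 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  sq <- as.matrix(stats::dist(Xs))^2

  chol_jitter <- function(K) {
    for (j in c(0, 1e-10, 1e-8, 1e-6)) {
      R <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
      if (!is.null(R)) return(R)
    }
    stop("kernel factorization failed even with jitter", call. = FALSE)
  }

  neg_lml <- function(logp) {
    p <- exp(logp)
    K <- p[2] * exp(-sq / (2 * p[1]^2)) + diag(p[3], N)
    R <- tryCatch(chol(K + diag(1e-10, N)), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    a <- backsolve(R, forwardsolve(t(R), ys))
    0.5 * sum(ys * a) + sum(log(diag(R))) + 0.5 * N * log(2 * pi)
  }
  neg_lml_grad <- function(logp) {
    p <- exp(logp)
    Krbf <- exp(-sq / (2 * p[1]^2))
    K <- p[2] * Krbf + diag(p[3], N)
    R <- tryCatch(chol(K + diag(1e-10, N)), error = function(e) NULL)
    if (is.null(R)) return(c(0, 0, 0))
    Kinv <- chol2inv(R)
    a <- drop(Kinv %*% ys)
    A <- tcrossprod(a) - Kinv
    dK_dlscale <- p[2] * Krbf * sq / p[1]^2   # dK/d log(rbf_scale)
    dK_dlsv <- p[2] * Krbf                    # dK/d log(signal_var)
    g <- c(sum(A * dK_dlscale), sum(A * dK_dlsv), p[3] * sum(diag(A)))
    -0.5 * g
  }

  pars <- c(rbf_scale, signal_var, noise_level)
  if (isTRUE(optimize) && N > 2) {
    opt <- stats::optim(log(pars), neg_lml, gr = neg_lml_grad,
                        method = "L-BFGS-B",
                        lower = rep(log(1e-3), 3), upper = rep(log(1e3), 3),
                        control = list(maxit = 100))
    pars <- exp(opt$par)
  }

  K <- pars[2] * exp(-sq / (2 * pars[1]^2)) + diag(pars[3], N)
  R <- chol_jitter(K)
  alpha_vec <- backsolve(R, forwardsolve(t(R), ys))

  structure(list(Xtrain = Xs, alpha_vec = alpha_vec, chol_R = R,
                 kernel = list(rbf_scale = pars[1], signal_var = pars[2],
                               noise_level = pars[3]),
                 optimize_flag = isTRUE(optimize),
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf(
    "<gpr_model> N = %d, rbf_scale = %.3g, signal_var = %.3g, noise = %.3g%s\n",
    nrow(x$Xtrain), x$kernel$rbf_scale, x$kernel$signal_var,
    x$kernel$noise_level,
    if (x$optimize_flag) " (marginal-likelihood refined)" else " (fixed)"))
  invisible(x)
}

#' Posterior mean and SD of a Gaussian process regressor
#'
#' Standard GP posterior: `mean = k*' (K + noise I)^-1 y`, de-standardized;
#' the predictive SD comes from
#' `k(x, x) - k*' (K + noise I)^-1 k*` (noise-free latent variance, floored
#' at zero) scaled back to response units.
#'
#' @param model A `gpr_model` from [gpr_fit()].
#' @param x Query vector of length P or matrix of queries (rows).
#' @return A list with `mean` and `sd` (each of length = number of queries).
#' @export
gpr_predict <- function(model, x) {
  Xq <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(Xq) != ncol(model$Xtrain)) {
    stop("query dimension does not match the model", call. = FALSE)
  }
  Xqs <- sweep(sweep(Xq, 2, model$x_center), 2, model$x_scale, "/")
  kp <- model$kernel
  # squared distances query x train
  sq <- outer(rowSums(Xqs^2), rowSums(model$Xtrain^2), "+") -
    2 * Xqs %*% t(model$Xtrain)
  Kstar <- kp$signal_var * exp(-pmax(sq, 0) / (2 * kp$rbf_scale^2))
  mu <- drop(Kstar %*% model$alpha_vec) * model$y_scale + model$y_center
  v <- forwardsolve(t(model$chol_R), t(Kstar))
  var_lat <- pmax(0, kp$signal_var - colSums(v^2))
  list(mean = mu, sd = sqrt(var_lat) * model$y_scale)
}
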