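#' Mahalanobis distance between two feature vectors
#'
#' `d_m = sqrt((xi - xj)' S^-1 (xi - xj))` — a Euclidean distance corrected
#' for the differing scales and correlations of the explanatory features. An
#' ill-conditioned covariance is inverted through a ridge-regularized inverse
#' with ridge `1e-8 * trace(S) / P`.
#'
#' @param xi,xj Numeric vectors of length P.
#' @param S Symmetric P x P covariance matrix.
#' @return Non-negative distance.
#' @export
mahalanobis_distance <- function(xi, xj, S) {
  Sinv <- covariance_inverse(S)
  d <- xi - xj
  sqrt(max(0, drop(t(d) %*% Sinv %*% d)))
}

# Regularized inverse shared by the distance and similarity routines.
covariance_inverse <- function(S) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(abs(ev), 1)
  if (any(ev < -tol)) {
    stop("invalid covariance: negative eigenvalues", call. = FALSE)
  }
  P <- ncol(S)
  ridge <- 1e-8 * sum(diag(S)) / P
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv) || min(ev) < ridge) {
    inv <- solve(S + diag(ridge + tol, P))
  }
  inv
}

#' Similarity weights for locally weighted PLS
#'
#' Maps Mahalanobis distances from the query to each training sample into
#' similarities `u_i = exp(-d_i / (sigma_d * phi))`, where `sigma_d` is the
#' standard deviation of the M distances — the standard localization used in
#' just-in-time PLS. Small `phi` localizes sharply; `phi = Inf` gives uniform
#' weights and reduces the local model to global PLS.
#'
#' @param Xt Training matrix (M x P).
#' @param xr Query vector of length P.
#' @param S Covariance matrix for the distance metric.
#' @param phi Localization parameter (> 0; `Inf` allowed).
#' @return Numeric vector of M weights in `(0, 1]`.
#' @export
similarity_weights <- function(Xt, xr, S, phi = 1) {
  if (phi <= 0) stop("`phi` must be > 0", call. = FALSE)
  Xt <- as.matrix(Xt)
  Sinv <- covariance_inverse(S)
  Dm <- sweep(Xt, 2, xr)
  d <- sqrt(pmax(0, rowSums((Dm %*% Sinv) * Dm)))
  if (is.infinite(phi)) return(rep(1, nrow(Xt)))
  sigma_d <- stats::sd(d)
  if (!is.finite(sigma_d) || sigma_d <= 0) return(rep(1, nrow(Xt)))
  u <- exp(-d / (sigma_d * phi))
  if (all(u <= 1e-300)) stop("no usable neighbours: all weights underflow",
                             call. = FALSE)
  u
}

#' Locally weighted PLS query object
#'
#' Bundles the training data for just-in-time prediction: the model is refit
#' around every query with sample weights decaying in Mahalanobis distance
#' from the query. Training features and response are autoscaled once here;
#' the covariance `S` for the metric is computed from the (standardized)
#' training features.
#'
#' @param Xt Training features (M x P).
#' @param yt Training response (length M).
#' @param phi Localization parameter (default 1).
#' @param D Number of latent components (default 2).
#' @return An object of class `lwpls_query`.
#' @export
lwpls_query <- function(Xt, yt, phi = 1, D = 2) {
  Xt <- as.matrix(Xt)
  yt <- as.numeric(yt)
  M <- nrow(Xt)
  if (length(yt) != M) stop("length(yt) must equal nrow(Xt)", call. = FALSE)
  if (M < D + 1) stop("need at least D + 1 training samples", call. = FALSE)
  x_center <- colMeans(Xt)
  x_scale <- apply(Xt, 2, stats::sd)
  if (any(x_scale <= 0)) {
    stop("constant explanatory column: cannot autoscale", call. = FALSE)
  }
  y_center <- mean(yt)
  y_scale <- stats::sd(yt)
  if (y_scale <= 0) stop("constant response: cannot autoscale", call. = FALSE)
  Xs <- sweep(sweep(Xt, 2, x_center), 2, x_scale, "/")
  S <- stats::cov(Xs)
  structure(list(Xs = Xs, ys = (yt - y_center) / y_scale,
                 phi = phi, D = D, S = S,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale),
            class = "lwpls_query")
}

#' Predict one query with locally weighted PLS
#'
#' Builds the diagonal similarity matrix from [similarity_weights()], centers
#' the training data at the similarity-weighted means, then extracts weighted
#' PLS components: `w_a = X0' U y0 / ||X0' U y0||`, `t_a = X0 w_a`,
#' `p_a = X0' U t_a / (t_a' U t_a)`, `q_a = y0' U t_a / (t_a' U t_a)`, with
#' deflation, projecting the centered query alongside. The estimate is the
#' weighted mean response plus `sum(t_r,a q_a)`. When a component degenerates
#' (weight mass concentrated on coincident samples) extraction stops early
#' and the estimate uses the components found so far, which yields the
#' nearest-neighbour limit under extreme localization.
#'
#' @param query An [lwpls_query()].
#' @param xr Query feature vector of length P.
#' @return Predicted response (de-standardized scalar).
#' @export
lwpls_predict <- function(query, xr) {
  stopifnot(inherits(query, "lwpls_query"))
  if (length(xr) != ncol(query$Xs)) {
    stop("query dimension does not match the training data", call. = FALSE)
  }
  xs <- (xr - query$x_center) / query$x_scale
  u <- similarity_weights(query$Xs, xs, query$S, query$phi)

  su <- sum(u)
  xw <- drop(crossprod(query$Xs, u)) / su
  yw <- sum(u * query$ys) / su
  X0 <- sweep(query$Xs, 2, xw)
  y0 <- query$ys - yw
  x0 <- xs - xw

  yhat <- yw
  for (a in seq_len(query$D)) {
    cov_xy <- drop(crossprod(X0, u * y0))
    nrm <- sqrt(sum(cov_xy^2))
    if (nrm < 1e-12) break
    w <- cov_xy / nrm
    t_a <- drop(X0 %*% w)
    tut <- sum(u * t_a^2)
    if (tut < 1e-12) break
    p <- drop(crossprod(X0, u * t_a)) / tut
    q <- sum(u * y0 * t_a) / tut
    t_r <- sum(x0 * w)
    yhat <- yhat + t_r * q
    X0 <- X0 - tcrossprod(t_a, p)
    y0 <- y0 - t_a * q
    x0 <- x0 - t_r * p
  }
  yhat * query$y_scale + query$y_center
}
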