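#' Error metrics for one evaluation cell
#'
#' Error is `pred - ref`. Reports the mean absolute error (MAE), the mean
#' error (ME, the bias), the error SD (denominator n - 1), the RMSE, the
#' Pearson correlation between prediction and reference, and Bland-Altman
#' agreement limits `ME +/- 1.96 SD`. The correlation is reported as missing
#' (not zero) when either side has zero variance.
#'
#' @param pred,ref Numeric vectors of equal length (n >= 2); `NA` pairs are
#'   dropped.
#' @return A one-row data frame: n, mae, me, sd, rmse, pearson_r,
#'   ba_lower, ba_upper.
#' @export
compute_metrics <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("`pred` and `ref` must have equal length", call. = FALSE)
  }
  ok <- is.finite(pred) & is.finite(ref)
  pred <- pred[ok]; ref <- ref[ok]
  n <- length(pred)
  if (n < 2) stop("need at least 2 prediction/reference pairs", call. = FALSE)
  err <- pred - ref
  me <- mean(err)
  s <- stats::sd(err)
  r <- if (stats::sd(pred) > 0 && stats::sd(ref) > 0) {
    stats::cor(pred, ref)
  } else {
    NA_real_
  }
  data.frame(n = n, mae = mean(abs(err)), me = me, sd = s,
             rmse = sqrt(mean(err^2)), pearson_r = r,
             ba_lower = me - 1.96 * s, ba_upper = me + 1.96 * s)
}

#' Paired comparison of two models' per-subject MAEs
#'
#' Two-sided paired Student t-test across subjects on per-subject MAE lists,
#' as used to compare the lowest-MAE model against close competitors. No
#' multiple-testing correction is applied; raw p-values are reported.
#'
#' @param mae_a,mae_b Named numeric vectors of per-subject MAE (same
#'   subjects, same order or name-matchable).
#' @param label_a,label_b Model labels for the verdict.
#' @return A list with `t`, `p`, `lower` (label of the model with the lower
#'   mean MAE), `mean_diff` (`mean(a) - mean(b)`), and `small_sample`
#'   (TRUE when fewer than 3 subjects).
#' @export
compare_models <- function(mae_a, mae_b, label_a = "A", label_b = "B") {
  if (!is.null(names(mae_a)) && !is.null(names(mae_b))) {
    if (!setequal(names(mae_a), names(mae_b))) {
      stop("the two MAE lists cover different subject sets", call. = FALSE)
    }
    mae_b <- mae_b[names(mae_a)]
  } else if (length(mae_a) != length(mae_b)) {
    stop("the two MAE lists cover different subject sets", call. = FALSE)
  }
  d <- mae_a - mae_b
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(mae_a, mae_b, paired = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       lower = if (mean(d) <= 0) label_a else label_b,
       mean_diff = mean(d),
       small_sample = length(mae_a) < 3)
}

#' Intra- versus inter-subject similarity distributions
#'
#' Computes the Mahalanobis-distance-based similarity (the same exponential
#' map as [similarity_weights()], `phi = 1`, pooled within-subject
#' covariance) for pairs of samples from the same subject and for pairs from
#' different subjects. A higher intra-subject than inter-subject similarity
#' with partial overlap is the structural reason individual models beat
#' generalized ones: kernel-based regressors recruit other subjects' nearby
#' samples whose BP mapping differs.
#'
#' @param feature_table Output of [extract_feature_table()].
#' @param set_id Feature set defining the similarity space.
#' @param phi Localization parameter of the similarity map.
#' @param max_pairs Cap on sampled pairs per distribution.
#' @param seed Seed for pair subsampling.
#' @return A list with `intra`, `inter` (similarity samples), their medians,
#'   and `n_subjects`.
#' @export
similarity_histograms <- function(feature_table, set_id = "set1", phi = 1,
                                  max_pairs = 1e5, seed = 1) {
  cols <- feature_set(set_id)
  keep <- !feature_table$rejected &
    stats::complete.cases(feature_table[, cols, drop = FALSE])
  ft <- feature_table[keep, , drop = FALSE]
  X <- as.matrix(ft[, cols, drop = FALSE])
  id <- as.character(ft$subject_id)
  subjects <- unique(id)

  # pooled within-subject covariance (df-weighted)
  parts <- lapply(subjects, function(s) {
    Xi <- X[id == s, , drop = FALSE]
    if (nrow(Xi) < 2) return(NULL)
    list(S = stats::cov(Xi), df = nrow(Xi) - 1)
  })
  parts <- Filter(Negate(is.null), parts)
  S <- Reduce(`+`, lapply(parts, function(p) p$S * p$df)) /
    sum(vapply(parts, `[[`, numeric(1), "df"))
  Sinv <- covariance_inverse(S)
  L <- chol(Sinv)
  Z <- X %*% t(L)  # Euclidean distance in Z = Mahalanobis distance in X

  pair_dist <- function(i, j) sqrt(rowSums((Z[i, , drop = FALSE] -
                                              Z[j, , drop = FALSE])^2))
  withr::with_seed(seed, {
    n <- nrow(Z)
    same <- outer(id, id, "==")
    ut <- which(upper.tri(same))
    intra_p <- ut[same[ut]]
    inter_p <- ut[!same[ut]]
    if (length(intra_p) > max_pairs) intra_p <- sample(intra_p, max_pairs)
    if (length(inter_p) > max_pairs) inter_p <- sample(inter_p, max_pairs)
    ij <- function(k) cbind((k - 1) %% n + 1, (k - 1) %/% n + 1)
    d_intra <- if (length(intra_p)) {
      m <- ij(intra_p); pair_dist(m[, 1], m[, 2])
    } else numeric(0)
    d_inter <- if (length(inter_p)) {
      m <- ij(inter_p); pair_dist(m[, 1], m[, 2])
    } else numeric(0)
    sigma_d <- stats::sd(c(d_intra, d_inter))
    to_sim <- function(d) if (sigma_d > 0) exp(-d / (sigma_d * phi)) else
      rep(1, length(d))
    list(intra = to_sim(d_intra), inter = to_sim(d_inter),
         median_intra = stats::median(to_sim(d_intra)),
         median_inter = if (length(d_inter)) {
           stats::median(to_sim(d_inter))
         } else NA_real_,
         n_subjects = length(subjects),
         single_subject = length(subjects) < 2)
  })
}
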