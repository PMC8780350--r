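#' Initial-only calibration scheme (scheme_1)
#'
#' Uses the first 20% of a subject's time-ordered samples as the calibration
#' set: a single window `[1, round(0.2 * n)]` (round-half-up, so 23 samples
#' at n = 115). Indices are 1-based and inclusive throughout.
#'
#' @param n Number of usable samples for the subject (>= 10).
#' @return An object of class `calibration_scheme`.
#' @export
scheme1_indices <- function(n) {
  n <- as.integer(n)
  if (n < 10) stop("too few samples for scheme_1 (need >= 10)", call. = FALSE)
  end <- floor(0.2 * n + 0.5)  # round-half-up
  new_scheme("scheme_1", list(c(1L, as.integer(end))), n)
}

#' Intermittent re-calibration scheme (scheme_2)
#'
#' Uses the first 4% of the samples (round-half-up, so 5 samples at
#' n = 115) plus
#' the fixed windows 15th-18th, 35th-38th, 55th-58th, 75th-78th and 95th-98th
#' — roughly 20% of the samples in total, spread over the month so the model
#' can be re-calibrated as slow BP trends accumulate. Windows starting beyond
#' `n` are dropped; a window overrunning `n` is truncated.
#'
#' @param n Number of usable samples for the subject (>= 18).
#' @return An object of class `calibration_scheme`.
#' @export
scheme2_indices <- function(n) {
  n <- as.integer(n)
  if (n < 18) stop("too few samples for scheme_2 (need >= 18)", call. = FALSE)
  wins <- list(c(1L, max(1L, as.integer(floor(0.04 * n + 0.5)))))
  for (s in c(15L, 35L, 55L, 75L, 95L)) {
    if (s > n) break
    wins[[length(wins) + 1L]] <- c(s, min(s + 3L, n))
  }
  new_scheme("scheme_2", wins, n)
}

new_scheme <- function(kind, windows, n) {
  ends <- vapply(windows, `[`, integer(1), 2L)
  starts <- vapply(windows, `[`, integer(1), 1L)
  stopifnot(all(starts <= ends), all(ends <= n),
            !is.unsorted(starts), all(starts[-1] > ends[-length(ends)]))
  structure(list(kind = kind, windows = windows, n = as.integer(n)),
            class = "calibration_scheme")
}

#' @export
print.calibration_scheme <- function(x, ...) {
  w <- paste(vapply(x$windows, function(v) paste(v, collapse = "-"),
                    character(1)), collapse = ", ")
  cat(sprintf("<%s> n = %d, calibration windows: %s (%d samples)\n",
              x$kind, x$n, w, length(scheme_calibration_indices(x))))
  invisible(x)
}

#' All calibration indices of a scheme
#' @param scheme A `calibration_scheme`.
#' @return Sorted integer vector of calibration sample indices.
#' @export
scheme_calibration_indices <- function(scheme) {
  sort(unique(unlist(lapply(scheme$windows, function(w) w[1]:w[2]))))
}

#' Per-subject time-ordered dataset
#'
#' Assembles the ordered (feature, BP) samples of one subject from a tidy
#' feature table, dropping rejected sessions. Sample indices are 1-based and
#' contiguous over the usable samples, matching the ordinal convention of the
#' calibration schemes.
#'
#' @param feature_table Output of [extract_feature_table()].
#' @param set_id Feature set (`"set1"`, `"set2"`, `"set3"`).
#' @param target `"sbp"` or `"dbp"`.
#' @return A list of `subject_dataset` objects, one per subject, each with
#'   `subject_id`, `X` (n x P feature matrix), `y` (reference BP), `timestamp`
#'   and `n`.
#' @export
subject_datasets <- function(feature_table, set_id = "set1",
                             target = c("sbp", "dbp")) {
  target <- match.arg(target)
  cols <- feature_set(set_id)
  ycol <- if (target == "sbp") "sbp_ref" else "dbp_ref"
  keep <- !feature_table$rejected &
    stats::complete.cases(feature_table[, cols, drop = FALSE])
  ft <- feature_table[keep, , drop = FALSE]
  lapply(split(ft, ft$subject_id), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    structure(list(subject_id = d$subject_id[1],
                   X = as.matrix(d[, cols, drop = FALSE]),
                   y = d[[ycol]], timestamp = d$timestamp, n = nrow(d)),
              class = "subject_dataset")
  })
}

#' Rolling, leakage-free prediction under a calibration scheme
#'
#' Predicts every non-calibration sample of a subject using only calibration
#' windows that lie entirely before it, so no future reference reading ever
#' enters training. A fresh model is fit per contiguous test segment (the
#' available windows change only at window boundaries). Under the
#' `"generalized"` strategy, all samples of every other subject are added to
#' each training set; under `"individual"` only the subject's own calibration
#' samples are used. Test samples with no preceding calibration window are
#' reported as unpredictable, never silently imputed.
#'
#' @param ds A `subject_dataset`.
#' @param scheme A `calibration_scheme` valid for `ds$n`.
#' @param model_factory Function `(X, y) -> function(Xnew) -> numeric`, e.g.
#'   [pls_factory()].
#' @param strategy `"individual"` or `"generalized"`.
#' @param others For `"generalized"`: non-empty list of the other subjects'
#'   `subject_dataset`s.
#' @return A data frame with one row per test index: `index`, `pred`, `ref`,
#'   `n_train`, `max_cal_index` (largest own calibration index used) and
#'   `predictable`. The training subject labels are attached as the
#'   `"train_subjects"` attribute for audit.
#' @export
rolling_predict <- function(ds, scheme, model_factory,
                            strategy = c("individual", "generalized"),
                            others = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(ds, "subject_dataset"),
            inherits(scheme, "calibration_scheme"))
  if (scheme$n != ds$n) {
    stop("scheme was built for a different sample count", call. = FALSE)
  }
  if (strategy == "generalized" && !length(others)) {
    stop("generalized strategy requires the other subjects' datasets",
         call. = FALSE)
  }

  cal <- scheme_calibration_indices(scheme)
  test_idx <- setdiff(seq_len(ds$n), cal)
  ends <- vapply(scheme$windows, `[`, integer(1), 2L)

  X_other <- NULL; y_other <- NULL
  if (strategy == "generalized") {
    X_other <- do.call(rbind, lapply(others, `[[`, "X"))
    y_other <- unlist(lapply(others, `[[`, "y"), use.names = FALSE)
  }

  # contiguous test segments sharing the same set of available windows
  n_avail <- vapply(test_idx, function(i) sum(ends < i), integer(1))
  seg <- cumsum(c(1L, diff(n_avail) != 0 | diff(test_idx) != 1L))

  out <- data.frame(index = test_idx, pred = NA_real_, ref = ds$y[test_idx],
                    n_train = 0L, max_cal_index = NA_integer_,
                    predictable = FALSE)
  for (g in unique(seg)) {
    rows <- which(seg == g)
    k <- n_avail[rows[1]]
    if (k == 0L) next  # no prior calibration window: unpredictable
    cal_idx <- unlist(lapply(scheme$windows[seq_len(k)],
                             function(w) w[1]:w[2]))
    Xtr <- ds$X[cal_idx, , drop = FALSE]
    ytr <- ds$y[cal_idx]
    if (!is.null(X_other)) {
      Xtr <- rbind(X_other, Xtr)
      ytr <- c(y_other, ytr)
    }
    predict_fun <- tryCatch(model_factory(Xtr, ytr), error = function(e) NULL)
    if (is.null(predict_fun)) next
    pr <- tryCatch(
      as.numeric(predict_fun(ds$X[test_idx[rows], , drop = FALSE])),
      error = function(e) rep(NA_real_, length(rows)))
    out$pred[rows] <- pr
    out$n_train[rows] <- length(ytr)
    out$max_cal_index[rows] <- max(cal_idx)
    out$predictable[rows] <- !is.na(pr)
  }
  attr(out, "train_subjects") <- if (strategy == "generalized") {
    c(vapply(others, `[[`, character(1), "subject_id"), ds$subject_id)
  } else {
    ds$subject_id
  }
  out
}

#' Linear-interpolation baseline between calibration windows
#'
#' Reference-only baseline for the intermittent scheme: each inter-window test
#' segment is predicted by linear interpolation, in sample index, between the
#' mean reference BP of the two flanking calibration windows (anchored at the
#' windows' center indices). Test samples after the last window extrapolate
#' the last window's mean as a constant. A model that cannot beat this
#' baseline learns nothing from the waveform.
#'
#' @param ds A `subject_dataset`.
#' @param scheme A `calibration_scheme` with at least two windows
#'   (normally [scheme2_indices()]).
#' @return Data frame with `index`, `pred`, `ref` for every test index.
#' @export
interpolation_baseline <- function(ds, scheme) {
  if (length(scheme$windows) < 2) {
    stop("interpolation baseline needs at least two calibration windows",
         call. = FALSE)
  }
  centers <- vapply(scheme$windows, function(w) mean(w[1]:w[2]), numeric(1))
  means <- vapply(scheme$windows, function(w) mean(ds$y[w[1]:w[2]]),
                  numeric(1))
  cal <- scheme_calibration_indices(scheme)
  test_idx <- setdiff(seq_len(ds$n), cal)
  pred <- vapply(test_idx, function(i) {
    j <- findInterval(i, centers)
    if (j >= length(centers)) return(means[length(means)])
    if (j < 1) return(means[1])
    means[j] + (means[j + 1] - means[j]) * (i - centers[j]) /
      (centers[j + 1] - centers[j])
  }, numeric(1))
  data.frame(index = test_idx, pred = pred, ref = ds$y[test_idx])
}

#' Model factories for the evaluation grid
#'
#' Each factory returns a function `(X, y)` that fits the model and returns a
#' prediction closure, the shape [rolling_predict()] expects.
#'
#' @param D Number of PLS latent components.
#' @param phi LW-PLS localization parameter.
#' @param optimize Refine GPR hyper-parameters by marginal likelihood?
#' @return A function `(X, y) -> function(Xnew) -> numeric`.
#' @rdname model_factories
#' @export
pls_factory <- function(D = 2) {
  function(X, y) {
    m <- pls_fit(X, y, D = min(D, ncol(as.matrix(X))))
    function(Xnew) pls_predict(m, as.matrix(Xnew))
  }
}

#' @rdname model_factories
#' @export
lwpls_factory <- function(D = 2, phi = 1) {
  function(X, y) {
    q <- lwpls_query(X, y, phi = phi, D = min(D, ncol(as.matrix(X))))
    function(Xnew) {
      Xnew <- as.matrix(Xnew)
      vapply(seq_len(nrow(Xnew)), function(i) lwpls_predict(q, Xnew[i, ]),
             numeric(1))
    }
  }
}

#' @rdname model_factories
#' @export
gpr_factory <- function(optimize = FALSE) {
  function(X, y) {
    m <- gpr_fit(X, y, optimize = optimize)
    function(Xnew) gpr_predict(m, as.matrix(Xnew))$mean
  }
}
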