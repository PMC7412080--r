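#' Windowed statistical features
#'
#' The seven per-channel statistics computed over each window's valid
#' (non-missing) samples. Conventions follow the printed defining formulas
#' exactly, which mixes divisors deliberately:
#'
#' * `feat_mean`: arithmetic mean.
#' * `feat_variance`: population variance, `mean((x - mean(x))^2)` (divisor
#'   `n`, the expectation form).
#' * `feat_skewness`: sample-adjusted skewness
#'   `n/((n-1)(n-2)) * sum(((x - mean)/S)^3)` with `S` the sample standard
#'   deviation (divisor `n - 1`). Requires `n >= 3` and `S > 0`.
#' * `feat_kurtosis`: adjusted excess kurtosis
#'   `n(n+1)/((n-1)(n-2)(n-3)) * sum(((x - mean)/S)^4) - 3(n-1)^2/((n-2)(n-3))`.
#'   Zero in the Gaussian limit. Requires `n >= 4` and `S > 0`.
#' * `feat_mad`: mean absolute deviation about the median,
#'   `mean(|x - median(x)|)`. (Often labeled "MAD" in the activity-recognition
#'   literature; note it is the mean, not the median, of the absolute
#'   deviations.)
#'
#' Each returns `NA_real_` when its own precondition fails (too few samples,
#' or zero spread for the standardized moments); callers treat `NA` as an
#' "undefined feature" flag, never as a value.
#'
#' @param x Numeric vector of valid samples (no `NA`s).
#' @return A single numeric value, or `NA_real_` if undefined.
#' @name window_stats
NULL

#' @rdname window_stats
#' @export
feat_mean <- function(x) {
  if (length(x) < 1L) return(NA_real_)
  sum(x) / length(x)
}

#' @rdname window_stats
#' @export
feat_variance <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  m <- sum(x) / n
  sum((x - m)^2) / n
}

#' @rdname window_stats
#' @export
feat_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' @rdname window_stats
#' @export
feat_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) *
    sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' @rdname window_stats
#' @export
feat_mad <- function(x) {
  if (length(x) < 1L) return(NA_real_)
  mean(abs(x - stats::median(x)))
}

# Stat-major feature layout: all means, then all variances, ... matching the
# conventional 21-feature table for tri-axial data (7 per channel).
.feature_stats <- c(mean = "feat_mean", var = "feat_variance",
                    skew = "feat_skewness", kurt = "feat_kurtosis",
                    max = "max", min = "min", mad = "feat_mad")

feature_names <- function(channels) {
  as.vector(t(outer(names(.feature_stats), channels, paste, sep = "_")))
}

#' Extract the windowed feature vector of one window
#'
#' Computes the seven statistics per channel (21 features for tri-axial
#' input, 7 for single-channel) over the window's valid rows only: masked
#' rows are skipped entirely, so the result equals the same statistics of the
#' explicitly-subsetted valid subsequence — no sentinel value ever enters the
#' arithmetic, and no imputation is performed. A statistic whose own
#' precondition fails is `NA` (undefined); a window with fewer than
#' `min_valid` surviving samples is entirely undefined.
#'
#' @param window One element of [segment_windows()] output.
#' @param min_valid Minimum valid samples for the window to be featurized.
#' @return Named numeric vector in fixed stat-major order
#'   (`mean_x, mean_y, mean_z, var_x, ...`).
#' @export
extract_features <- function(window, min_valid = 4L) {
  vals <- window$values[!window$row_missing, , drop = FALSE]
  channels <- colnames(vals)
  out <- rep(NA_real_, length(.feature_stats) * length(channels))
  names(out) <- feature_names(channels)
  if (nrow(vals) >= min_valid) {
    for (ch in channels) {
      x <- vals[, ch]
      for (st in names(.feature_stats))
        out[paste(st, ch, sep = "_")] <- do.call(.feature_stats[[st]], list(x))
    }
  }
  out
}

#' Build a feature table from one or more sensor series
#'
#' Segments each recording with `config` (windows never span recordings) and
#' extracts the windowed statistics, returning one row per window with the
#' metadata columns `subject_id`, `window_start`, `label`, `n_valid` followed
#' by the feature columns in fixed order.
#'
#' @param series A [sensor_series()] or a list of them.
#' @param config A [window_config()].
#' @return A `data.frame` of class `har_features` with attribute
#'   `feature_cols` naming the feature columns.
#' @examples
#' d <- build_simulated_dataset(n_per_class = 100)
#' head(featurize(d$train, window_config(1, 0.5)))
#' @export
featurize <- function(series, config = window_config()) {
  if (inherits(series, "sensor_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, TRUE, "sensor_series")))
  rows <- list()
  for (s in series) {
    wins <- segment_windows(s, config)
    for (w in wins) {
      fv <- extract_features(w, min_valid = config$min_valid_samples)
      rows[[length(rows) + 1L]] <- c(
        list(subject_id = w$subject_id, window_start = w$start,
             label = w$label, n_valid = w$n_valid),
        as.list(fv)
      )
    }
  }
  if (!length(rows)) {
    fcols <- feature_names(colnames(series[[1L]]$values))
    out <- as.data.frame(c(list(subject_id = character(),
                                window_start = numeric(),
                                label = character(), n_valid = integer()),
                           stats::setNames(rep(list(numeric()), length(fcols)),
                                           fcols)))
  } else {
    out <- do.call(rbind, lapply(rows, as.data.frame))
    fcols <- setdiff(names(out),
                     c("subject_id", "window_start", "label", "n_valid"))
  }
  structure(out, feature_cols = fcols, class = c("har_features", "data.frame"))
}

# Keep the feature_cols attribute through [ subsetting used internally.
#' @export
`[.har_features` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "feature_cols") <- intersect(attr(x, "feature_cols"), names(out))
    class(out) <- c("har_features", "data.frame")
  }
  out
}

#' Training-median fill for undefined features
#'
#' Degenerate windows (too few valid samples, or zero spread) yield undefined
#' entries that classifiers cannot consume. This policy replaces each
#' undefined entry with the per-feature median computed once from the
#' TRAINING feature table and frozen, so no information flows from test data
#' and no raw-signal imputation takes place — only the rectangularization of
#' the feature matrix. A feature undefined on every training window falls
#' back to 0.
#'
#' @param features A `har_features` table.
#' @param medians Named vector of frozen fill values; `NULL` (training time)
#'   computes them from `features` itself.
#' @return List with the filled numeric feature `matrix`, the `medians` used
#'   and the `labels`.
#' @export
fill_undefined <- function(features, medians = NULL) {
  fcols <- attr(features, "feature_cols")
  x <- as.matrix(features[, fcols, drop = FALSE])
  if (is.null(medians)) {
    medians <- apply(x, 2L, stats::median, na.rm = TRUE)
    medians[!is.finite(medians)] <- 0
  }
  for (j in seq_along(fcols)) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- medians[[fcols[j]]]
  }
  list(matrix = x, medians = medians, labels = features$label)
}
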