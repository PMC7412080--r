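#' Construct a sensor series
#'
#' A `sensor_series` is the package's container for a single recording from a
#' body-worn accelerometer: a strictly time-ordered set of samples on one or
#' three channels, with an explicit per-row missingness flag. Missingness is
#' always whole-row: a dropped timestep loses every channel simultaneously,
#' which is how sample loss manifests in a sensor stream (the transmission
#' unit is the full tuple, not an individual axis). The flag — not a sentinel
#' value — is the authoritative record of what is missing, so masked values
#' can never leak into feature arithmetic.
#'
#' @param values Numeric vector (single channel) or matrix/data.frame with
#'   columns `x`, `y`, `z` (tri-axial). Rows that are entirely `NA` are
#'   recorded as missing; partially-`NA` rows are rejected.
#' @param timestamps Numeric vector of seconds from recording start,
#'   non-decreasing. If `NULL`, synthesized as `(0:(n-1))/sampling_rate`.
#' @param sampling_rate Nominal sampling rate in Hz. If `NULL` and timestamps
#'   are supplied, it is estimated as `1/median(diff(timestamps))`.
#' @param labels Per-row activity labels (character), or a single label
#'   applied to the whole recording, or `NULL`.
#' @param subject_id Identifier of the person the recording belongs to.
#'
#' @return An object of class `sensor_series`: a list with elements
#'   `timestamps`, `values` (an n-by-k numeric matrix), `row_missing`
#'   (logical), `labels`, `subject_id` and `sampling_rate`.
#' @examples
#' s <- sensor_series(cbind(x = rnorm(100), y = rnorm(100), z = rnorm(100)),
#'                    sampling_rate = 50, labels = "walk", subject_id = "s01")
#' s
#' missing_rate(s)
#' @export
sensor_series <- function(values, timestamps = NULL, sampling_rate = NULL,
                          labels = NULL, subject_id = NA_character_) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.null(dim(values))) {
    values <- matrix(as.numeric(values), ncol = 1L,
                     dimnames = list(NULL, "v"))
  }
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (n < 1L) stop("a sensor series needs at least one sample", call. = FALSE)
  if (is.null(colnames(values))) {
    colnames(values) <- if (ncol(values) == 3L) c("x", "y", "z") else
      paste0("v", if (ncol(values) > 1L) seq_len(ncol(values)) else "")
  }

  if (is.null(timestamps)) {
    if (is.null(sampling_rate))
      stop("supply either timestamps or a sampling_rate", call. = FALSE)
    timestamps <- (seq_len(n) - 1) / sampling_rate
  }
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != n)
    stop("timestamps and values must have the same length", call. = FALSE)
  if (any(diff(timestamps) < 0))
    stop("timestamps must be non-decreasing", call. = FALSE)
  if (is.null(sampling_rate)) {
    sampling_rate <- if (n > 1L) 1 / stats::median(diff(timestamps)) else NA_real_
  }

  na_count <- rowSums(is.na(values))
  if (any(na_count > 0L & na_count < ncol(values)))
    stop("rows must be entirely observed or entirely missing", call. = FALSE)
  row_missing <- na_count == ncol(values)

  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) == 1L) labels <- rep(labels, n)
    if (length(labels) != n)
      stop("labels must be length 1 or one per row", call. = FALSE)
  }

  structure(
    list(timestamps = timestamps, values = values, row_missing = row_missing,
         labels = labels, subject_id = as.character(subject_id),
         sampling_rate = sampling_rate),
    class = "sensor_series"
  )
}

#' Number of samples in a sensor series
#' @param series A [sensor_series()].
#' @return Integer sample count.
#' @export
n_samples <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  nrow(series$values)
}

#' Duration of a recording in seconds
#'
#' Each sample is taken to cover one nominal sampling period, so a recording
#' of n samples at fs Hz spans n/fs seconds; equivalently the timestamp span
#' plus one period. Without a nominal rate the raw span is returned. This is
#' the duration the windowing stage uses, so a 20 s recording yields the full
#' complement of windows rather than losing the trailing period.
#'
#' @param series A [sensor_series()].
#' @return Duration in seconds.
#' @export
series_duration <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  span <- series$timestamps[n_samples(series)] - series$timestamps[1L]
  if (is.finite(series$sampling_rate) && !is.na(series$sampling_rate))
    span + 1 / series$sampling_rate
  else span
}

#' Fraction of fully-missing rows
#'
#' @param series A [sensor_series()].
#' @return The observed missing rate, `(# fully-missing rows) / n`.
#' @export
missing_rate <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  mean(series$row_missing)
}

#' @export
print.sensor_series <- function(x, ...) {
  k <- ncol(x$values)
  cat(sprintf("<sensor_series> %d samples x %d channel%s (%s)\n",
              n_samples(x), k, if (k > 1) "s" else "",
              paste(colnames(x$values), collapse = ",")))
  cat(sprintf("  duration %.3f s, nominal rate %s Hz, missing %.1f%%\n",
              series_duration(x),
              if (is.na(x$sampling_rate)) "?" else
                format(x$sampling_rate, digits = 4),
              100 * missing_rate(x)))
  if (!is.null(x$labels))
    cat("  labels:", paste(unique(x$labels), collapse = ", "), "\n")
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive `n` child seeds from one parent seed, all < 2^31, deterministic.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
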