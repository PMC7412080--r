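#' Induce missing-at-random sample loss in a sensor series
#'
#' Masks exactly `round(rate * n)` rows of the series, chosen uniformly at
#' random without replacement under `seed`. A masked row loses every channel
#' simultaneously (the transmission tuple is lost whole); its timestamp is
#' retained, and all unmasked rows are left bit-identical. Selection depends
#' only on row position, never on the signal values, so the mechanism is
#' missing-at-random by construction: the probability that a sample is lost
#' is unrelated to what the lost sample contained.
#'
#' No imputation is ever performed on the result; downstream feature
#' extraction simply skips masked rows.
#'
#' @param series A [sensor_series()].
#' @param rate Target missing fraction in `[0, 1)`.
#' @param seed Integer seed for the mask draw.
#' @return The series with `round(rate * n)` additional rows masked.
#' @examples
#' s <- generate_pattern(waveform_spec("sine", n_samples = 100))
#' missing_rate(induce_mar(s, 0.1, seed = 7))
#' @export
induce_mar <- function(series, rate, seed = 1L) {
  stopifnot(inherits(series, "sensor_series"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("rate must be a single number in [0, 1)", call. = FALSE)
  n <- n_samples(series)
  m <- round(rate * n)
  if (m == 0) return(series)
  idx <- with_seed(seed, sample.int(n, m))
  series$values[idx, ] <- NA_real_
  series$row_missing[idx] <- TRUE
  series
}

#' Timestamp-gap missingness diagnostics
#'
#' Reconstructs how many samples a regularly-sampled stream lost from its
#' timestamps alone. Consecutive timestamp differences are assigned to the
#' nearest integer multiple `k` of the nominal sampling period, within
#' `jitter_tolerance`; a gap at multiple `k` implies `k - 1` consecutively
#' dropped samples (one sample missing on a 200 ms stream shows up as a
#' 400 ms gap, two as 600 ms, and so on). Gaps beyond `max_multiple` periods
#' are pooled into a `long_outage` bin — counted and reported, but excluded
#' from the random-loss ratios, since an extended outage is a different
#' failure mechanism (link or node down) than random sample loss. Gaps that
#' match no multiple within tolerance land in an `irregular` bin.
#'
#' @param timestamps Strictly increasing arrival times in milliseconds.
#' @param nominal_period Nominal sampling period in milliseconds (> 0).
#' @param jitter_tolerance Half-width in ms of the acceptance band around
#'   each period multiple. Default `nominal_period / 10`.
#' @param max_multiple Largest multiple treated as quantifiable random loss
#'   (default 5).
#' @return A `gap_report`: gap histogram (counts at multiples `1..k`, plus
#'   `irregular` and `long_outage`), per-bin missing ratios, the implied
#'   number of dropped samples, and the overall missing ratio
#'   `implied / (received + implied)`.
#' @examples
#' gap_histogram(c(0, 200, 400, 800), nominal_period = 200,
#'               jitter_tolerance = 20)
#' @export
gap_histogram <- function(timestamps, nominal_period,
                          jitter_tolerance = nominal_period / 10,
                          max_multiple = 5L) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) < 2L)
    stop("need at least two timestamps", call. = FALSE)
  gaps <- diff(timestamps)
  if (any(gaps <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (nominal_period <= 0) stop("nominal_period must be > 0", call. = FALSE)

  k <- pmax(1L, as.integer(round(gaps / nominal_period)))
  regular <- abs(gaps - k * nominal_period) <= jitter_tolerance
  long <- regular & k > max_multiple

  bins <- seq_len(max_multiple)
  counts <- vapply(bins, function(b) sum(regular & !long & k == b), 0L)
  names(counts) <- as.character(bins)
  n_irregular <- sum(!regular)
  n_long <- sum(long)

  received <- length(timestamps)
  implied_per_bin <- (bins - 1L) * counts
  implied <- sum(implied_per_bin)
  denom <- received + implied
  per_bin_ratio <- implied_per_bin / denom
  names(per_bin_ratio) <- names(counts)

  structure(
    list(histogram = counts, irregular = n_irregular, long_outage = n_long,
         per_bin_missing_ratio = per_bin_ratio,
         implied_missing = implied,
         overall_missing_ratio = implied / denom,
         n_received = received,
         nominal_period = nominal_period,
         jitter_tolerance = jitter_tolerance,
         max_multiple = as.integer(max_multiple)),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d samples received, nominal period %g ms\n",
              x$n_received, x$nominal_period))
  hdr <- sprintf("%g ms (k=%s)", as.integer(names(x$histogram)) *
                   x$nominal_period, names(x$histogram))
  for (i in seq_along(x$histogram))
    cat(sprintf("  %-16s %6d gaps  missing ratio %.4f\n", hdr[i],
                x$histogram[i], x$per_bin_missing_ratio[i]))
  if (x$irregular > 0) cat(sprintf("  irregular        %6d gaps\n", x$irregular))
  if (x$long_outage > 0)
    cat(sprintf("  long outage (>%dT)%5d gaps (excluded from ratios)\n",
                x$max_multiple, x$long_outage))
  cat(sprintf("  implied dropped samples: %d; overall missing ratio %.4f\n",
              x$implied_missing, x$overall_missing_ratio))
  invisible(x)
}
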