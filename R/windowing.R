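#' Windowing configuration
#'
#' Fixed-duration windows advanced by a slide. With `slide_s < window_s`
#' consecutive windows overlap, which smooths activity transitions at window
#' margins; the default slide is half the window (50% overlap). A slide
#' larger than the window leaves unobserved gaps and is allowed with a
#' warning.
#'
#' @param window_s Window length in seconds (> 0). Typical values are 1, 1.5
#'   and 2 s. Default 1.
#' @param slide_s Slide (hop) in seconds (> 0). Default `window_s / 2`.
#' @param min_valid_samples Minimum number of non-missing samples a window
#'   must contain for its features to be defined (default 4, the smallest
#'   count at which all seven windowed statistics exist).
#' @return A `window_config` list.
#' @export
window_config <- function(window_s = 1, slide_s = window_s / 2,
                          min_valid_samples = 4L) {
  if (window_s <= 0 || slide_s <= 0)
    stop("window_s and slide_s must be > 0", call. = FALSE)
  if (slide_s > window_s)
    warning("slide_s > window_s leaves gaps between windows", call. = FALSE)
  structure(list(window_s = window_s, slide_s = slide_s,
                 min_valid_samples = as.integer(min_valid_samples)),
            class = "window_config")
}

#' Segment a sensor series into labeled windows
#'
#' Cuts the recording into half-open intervals `[start, start + window_s)`
#' anchored at the first timestamp and advanced by `slide_s`. Segmentation is
#' timestamp-driven, so the same physical window boundaries result whatever
#' the sampling rate. The number of windows is
#' `floor((T - window_s) / slide_s) + 1` for recording duration
#' `T >= window_s` (see [series_duration()]), else zero.
#'
#' Each window keeps every row whose timestamp falls in its interval —
#' masked rows included, so `n_valid <= n` records how much of the window
#' survived — and takes the modal per-row activity label, ties broken by
#' whichever tied label appears earliest in the window.
#'
#' @param series A [sensor_series()].
#' @param config A [window_config()].
#' @return A list of class `har_windows`; each element has `start`, `end`,
#'   `label`, `values` (rows in the window), `row_missing`, `n`, `n_valid`,
#'   plus the series' `subject_id`.
#' @examples
#' s <- generate_pattern(waveform_spec("sine", n_samples = 200))
#' length(segment_windows(s, window_config(1, 0.5)))
#' @export
segment_windows <- function(series, config = window_config()) {
  stopifnot(inherits(series, "sensor_series"),
            inherits(config, "window_config"))
  t <- series$timestamps
  t0 <- t[1L]
  total <- series_duration(series)
  if (total < config$window_s)
    return(structure(list(), class = "har_windows", config = config))
  n_win <- floor((total - config$window_s) / config$slide_s + 1e-9) + 1L
  starts <- t0 + (seq_len(n_win) - 1L) * config$slide_s

  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    lo <- starts[i]
    hi <- lo + config$window_s
    idx <- which(t >= lo & t < hi)
    labs <- if (!is.null(series$labels)) series$labels[idx] else NULL
    label <- if (length(labs)) {
      tab <- table(factor(labs, levels = unique(labs)))  # first-seen order
      names(tab)[which.max(tab)]                          # ties -> earliest
    } else NA_character_
    out[[i]] <- list(
      start = lo, end = hi, label = label,
      values = series$values[idx, , drop = FALSE],
      row_missing = series$row_missing[idx],
      n = length(idx), n_valid = sum(!series$row_missing[idx]),
      subject_id = series$subject_id
    )
  }
  structure(out, class = "har_windows", config = config)
}

#' @export
print.har_windows <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<har_windows> %d windows of %g s, slide %g s\n",
              length(x), cfg$window_s, cfg$slide_s))
  invisible(x)
}
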