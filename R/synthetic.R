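#' Specification of a synthetic periodic waveform
#'
#' Describes one single-channel periodic test signal. Three signal classes are
#' supported — sine, sawtooth and square — chosen because their windowed
#' statistics (notably variance and kurtosis) separate the classes perfectly
#' in the noise-free limit, which pins the clean-data recognition rate of the
#' downstream classifiers at 100%.
#'
#' @param kind One of `"sine"`, `"sawtooth"`, `"square"`.
#' @param frequency Waveform frequency in Hz (> 0). Default 1.
#' @param amplitude Peak amplitude in signal units. Default 1.
#' @param sampling_rate Sampling rate in Hz; must satisfy Nyquist
#'   (`>= 2 * frequency`). Default 50.
#' @param n_samples Number of samples to generate (>= 1).
#' @param noise_sd Standard deviation of additive Gaussian noise, in signal
#'   units. Default 0 (noise-free).
#' @param seed Integer seed controlling the noise draw.
#' @return A `waveform_spec` list.
#' @export
waveform_spec <- function(kind, frequency = 1, amplitude = 1,
                          sampling_rate = 50, n_samples = 400,
                          noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind, c("sine", "sawtooth", "square"))
  if (frequency <= 0) stop("frequency must be > 0", call. = FALSE)
  if (sampling_rate < 2 * frequency)
    stop("sampling_rate must be at least 2 * frequency (Nyquist)",
         call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, frequency = frequency, amplitude = amplitude,
                 sampling_rate = sampling_rate,
                 n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "waveform_spec")
}

#' Generate a labeled synthetic waveform
#'
#' Samples the waveform described by `spec` at uniform timestamps
#' `0, 1/fs, 2/fs, ...` and adds Gaussian noise drawn under `spec$seed`.
#' Deterministic: the same spec always yields a bit-identical series.
#'
#' The waveforms are, with phase `p = (t * f) mod 1`:
#' sine `A*sin(2*pi*f*t)`; sawtooth `A*(2p - 1)` (rising ramp from -A to A);
#' square `+A` for `p < 0.5`, else `-A`.
#'
#' @param spec A [waveform_spec()].
#' @return A single-channel [sensor_series()] labeled with `spec$kind`.
#' @examples
#' generate_pattern(waveform_spec("sine", n_samples = 8, sampling_rate = 4))
#' @export
generate_pattern <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  t <- (seq_len(spec$n_samples) - 1) / spec$sampling_rate
  p <- (t * spec$frequency) %% 1
  clean <- switch(spec$kind,
    sine     = spec$amplitude * sin(2 * pi * spec$frequency * t),
    sawtooth = spec$amplitude * (2 * p - 1),
    square   = ifelse(p < 0.5, spec$amplitude, -spec$amplitude)
  )
  noisy <- if (spec$noise_sd > 0) {
    clean + with_seed(spec$seed, stats::rnorm(spec$n_samples, 0, spec$noise_sd))
  } else clean
  sensor_series(noisy, timestamps = t, sampling_rate = spec$sampling_rate,
                labels = spec$kind, subject_id = "synthetic")
}

#' Build the three-waveform simulated dataset
#'
#' Generates the synthetic benchmark used throughout the package: three
#' periodic signal classes (sine, sawtooth, square) with `n_per_class` raw
#' samples each — 1200 samples in total at the default 400 — split into one
#' training and one test sequence per class, generated with distinct seeds so
#' the two partitions carry independent noise.
#'
#' @param n_per_class Raw samples per class across train and test (default
#'   400, i.e. 8 s per class at 50 Hz).
#' @param train_fraction Fraction of each class's samples allocated to the
#'   training sequence (default 0.5).
#' @param frequency,amplitude,sampling_rate,noise_sd Shared waveform
#'   parameters; see [waveform_spec()]. Defaults: 1 Hz, 1, 50 Hz, 0.05.
#' @param train_seed,test_seed Integer seeds for the noise in the training
#'   and test partitions.
#' @return A list with elements `train` and `test`, each a list of three
#'   single-channel [sensor_series()], one per class.
#' @examples
#' d <- build_simulated_dataset(n_per_class = 40)
#' sum(vapply(c(d$train, d$test), n_samples, 1L))
#' @export
build_simulated_dataset <- function(n_per_class = 400, train_fraction = 0.5,
                                    frequency = 1, amplitude = 1,
                                    sampling_rate = 50, noise_sd = 0.05,
                                    train_seed = 1L, test_seed = 2L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  n_train <- round(n_per_class * train_fraction)
  n_test <- n_per_class - n_train
  kinds <- c("sine", "sawtooth", "square")
  tr_seeds <- derive_seeds(train_seed, 3L)
  te_seeds <- derive_seeds(test_seed, 3L)
  mk <- function(kind, n, seed) {
    generate_pattern(waveform_spec(kind, frequency = frequency,
                                   amplitude = amplitude,
                                   sampling_rate = sampling_rate,
                                   n_samples = n, noise_sd = noise_sd,
                                   seed = seed))
  }
  list(
    train = stats::setNames(
      Map(mk, kinds, rep(n_train, 3L), as.list(tr_seeds)), kinds),
    test = stats::setNames(
      Map(mk, kinds, rep(n_test, 3L), as.list(te_seeds)), kinds)
  )
}
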