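# Deliberately naive, loop-based reference implementations of the five
# windowed statistics, kept independent of the package's vectorized code.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_variance <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}

oracle_sample_sd <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

oracle_skewness <- function(x) {
  n <- length(x)
  m <- oracle_mean(x)
  s <- oracle_sample_sd(x)
  acc <- 0
  for (v in x) acc <- acc + ((v - m) / s)^3
  n / ((n - 1) * (n - 2)) * acc
}

oracle_kurtosis <- function(x) {
  n <- length(x)
  m <- oracle_mean(x)
  s <- oracle_sample_sd(x)
  acc <- 0
  for (v in x) acc <- acc + ((v - m) / s)^4
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * acc -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

oracle_mad <- function(x) {
  med <- median(x)
  s <- 0
  for (v in x) s <- s + abs(v - med)
  s / length(x)
}

# Small tri-axial series with controllable labels, for windowing/feature
# tests; 1-second blocks at `fs` Hz.
make_triax_series <- function(n, fs = 10, labels = "walk", seed = 1,
                              subject = "s1") {
  set.seed(seed)
  sensor_series(cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n)),
                sampling_rate = fs, labels = labels, subject_id = subject)
}
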