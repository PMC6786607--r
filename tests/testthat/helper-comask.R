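# Shared test utilities: independent spectral/envelope oracles used to
# verify the synthesis code (kept deliberately separate from the package's
# own signal path).

# One-sided power spectrum: power per positive-frequency bin.
power_spectrum <- function(x, sample_rate) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  keep <- f <= sample_rate / 2
  tibble::tibble(freq = f[keep], power = (Mod(X[keep]) / n)^2)
}

# Fraction of total power inside [lo, hi] Hz.
band_power_fraction <- function(x, sample_rate, lo, hi) {
  ps <- power_spectrum(x, sample_rate)
  sum(ps$power[ps$freq >= lo & ps$freq <= hi]) / sum(ps$power)
}

# Magnitude of the analytic signal (FFT-based Hilbert envelope).
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Band-pass via hard FFT mask (oracle-side band extraction).
fft_bandpass <- function(x, sample_rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  f_mirror <- sample_rate - f
  keep <- (f >= lo & f <= hi) | (f_mirror >= lo & f_mirror <= hi)
  Re(stats::fft(X * keep, inverse = TRUE) / n)
}

# Envelope correlation of two narrowband signals over their central
# portion (edges excluded to avoid ramp/filter transients).
envelope_correlation <- function(x, y, trim_frac = 0.1) {
  n <- length(x)
  idx <- seq(floor(n * trim_frac), ceiling(n * (1 - trim_frac)))
  stats::cor(analytic_envelope(x)[idx], analytic_envelope(y)[idx])
}

# A minimal sweep_set wrapper for hand-built channel x time matrices.
as_sweeps <- function(..., sample_rate = 1024, window_ms = c(-150, 1050)) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) && !is.matrix(mats[[1]])) {
    mats <- mats[[1]]
  }
  mats <- lapply(mats, function(m) if (is.matrix(m)) m else rbind(m))
  data <- array(0, dim = c(nrow(mats[[1]]), ncol(mats[[1]]),
                           length(mats)))
  for (i in seq_along(mats)) data[, , i] <- mats[[i]]
  sweep_set(data, sample_rate = sample_rate, window_ms = window_ms)
}

# Epoch time axis matching the package's half-open sample grid.
epoch_times <- function(window_ms = c(-150, 1050), sample_rate = 1024) {
  off <- ms_window_to_offsets(window_ms, sample_rate)
  seq(off[1], off[2]) / sample_rate * 1000
}
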