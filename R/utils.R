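# Shared time-grid and envelope utilities.
#
# All millisecond -> sample conversions live here. Instants round toward
# zero; windows are half-open on the right, so a window [w0, w1) contains
# every integer sample index k with w0*fs/1000 <= k < w1*fs/1000.

#' Convert a time instant in milliseconds to a sample index
#'
#' Rounds toward zero, so instants slightly past a sample map back onto it
#' symmetrically around zero.
#'
#' @param ms Time in milliseconds (scalar or vector).
#' @param sample_rate Sampling rate in Hz.
#' @return Integer sample index (0-based offset from time zero).
#' @export
ms_to_sample <- function(ms, sample_rate) {
  as.integer(trunc(ms * sample_rate / 1000))
}

#' Convert a half-open millisecond window to inclusive sample offsets
#'
#' Returns the first and last integer sample index k satisfying
#' `w[1]*fs/1000 <= k < w[2]*fs/1000`.
#'
#' @param window Numeric length-2 vector, `c(start_ms, end_ms)`.
#' @param sample_rate Sampling rate in Hz.
#' @return Integer length-2 vector of inclusive sample offsets.
#' @export
ms_window_to_offsets <- function(window, sample_rate) {
  stopifnot(length(window) == 2, window[2] > window[1])
  lo <- ceiling(window[1] * sample_rate / 1000)
  hi <- ceiling(window[2] * sample_rate / 1000) - 1
  as.integer(c(lo, hi))
}

# Logical mask over a time axis (ms) for a half-open window [w0, w1).
window_mask <- function(times_ms, window) {
  times_ms >= window[1] & times_ms < window[2]
}

#' Raised-cosine onset/offset envelope
#'
#' Envelope of length `n` with `n_ramp`-sample raised-cosine ramps at both
#' ends; the first and last sample are exactly zero.
#'
#' @param n Total length in samples.
#' @param n_ramp Ramp length in samples.
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
raised_cosine_envelope <- function(n, n_ramp) {
  stopifnot(n > 2 * n_ramp, n_ramp >= 0)
  env <- rep(1, n)
  if (n_ramp > 0) {
    # ramp rises from exactly 0 at the first sample to 1 one sample past it
    up <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
    env[seq_len(n_ramp)] <- up
    env[n + 1 - seq_len(n_ramp)] <- up
  }
  env
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. With seed = NULL the global stream is
# used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-purpose sub-seed derived from one global seed, so the
# stimulus, staircase, EEG and rating streams are independently
# reproducible. Stays well below 2^31 for small global seeds.
substream_seed <- function(seed, stream) {
  offsets <- c(stimuli = 101L, staircase = 211L, eeg = 307L, ratings = 401L)
  stream <- match.arg(stream, names(offsets))
  as.integer((as.numeric(seed) * 7L + offsets[[stream]]) %% 2147483629)
}
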