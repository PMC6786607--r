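# Stimulus synthesis: the masked-tone stimuli of a combined comodulation
# masking release (CMR) / binaural masking level difference (BMLD) design.
#
# Six conditions arise from crossing three masker types — five 24-Hz noise
# bands with uncorrelated (UN) or comodulated (CM) envelopes, or one
# 824-Hz broadband band (BB) — with a 700-Hz signal at interaural phase
# difference (IPD) 0 (diotic) or 150 degrees (dichotic).

#' Names of the six stimulus conditions
#'
#' Masker type (UN, CM, BB) crossed with signal IPD (0 or 150 degrees).
#'
#' @return Character vector of condition labels.
#' @export
stimulus_conditions <- function() {
  c("UN_0", "CM_0", "BB_0", "UN_150", "CM_150", "BB_150")
}

#' Signal specification
#'
#' A ramped pure tone presented in the final part of the masker.
#'
#' @param frequency Tone frequency, Hz.
#' @param duration Tone duration, ms (includes ramps).
#' @param ramp Raised-cosine on/off ramp duration, ms.
#' @param ipd Interaural phase difference, degrees; the right channel leads.
#' @param level Tone level, dB SPL under the calibration convention;
#'   `-Inf` renders an absent signal.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(frequency = 700, duration = 300, ramp = 20,
                        ipd = 0, level = 50) {
  stopifnot(frequency > 0, duration > 2 * ramp, ipd >= 0, ipd < 360)
  structure(
    list(frequency = frequency, duration = duration, ramp = ramp,
         ipd = ipd, level = level),
    class = "signal_spec"
  )
}

#' Masker specification
#'
#' Either five narrowband noise bands (kinds `"UN"` and `"CM"`) or one
#' broadband noise band (kind `"BB"`), all presented diotically.
#'
#' @param kind One of `"UN"` (uncorrelated bands), `"CM"` (comodulated
#'   bands), `"BB"` (broadband).
#' @param band_centers Band center frequencies, Hz (multi-band kinds). One
#'   center must equal the signal frequency (the signal-centered band).
#' @param band_width Width of each narrow band, Hz.
#' @param band_level Level of each narrow band, dB SPL.
#' @param bb_width Width of the broadband masker, Hz.
#' @param bb_level Overall level of the broadband masker, dB SPL.
#' @param duration Masker duration, ms.
#' @param ramp Raised-cosine ramp duration, ms.
#' @param signal_frequency Signal frequency the masker is built around, Hz.
#' @param share_carrier_phase For `"CM"`: if `TRUE`, all bands also share
#'   the carrier phase (by default only the modulator is shared).
#' @return An object of class `masker_spec`.
#' @export
masker_spec <- function(kind = c("UN", "CM", "BB"),
                        band_centers = c(300, 400, 700, 1000, 1100),
                        band_width = 24, band_level = 50,
                        bb_width = 824, bb_level = 60,
                        duration = 900, ramp = 20,
                        signal_frequency = 700,
                        share_carrier_phase = FALSE) {
  kind <- match.arg(kind)
  stopifnot(band_width > 0, band_width %% 2 == 0, duration > 2 * ramp)
  if (kind %in% c("UN", "CM")) {
    if (sum(band_centers == signal_frequency) != 1) {
      stop("exactly one band center must equal the signal frequency (",
           signal_frequency, " Hz)")
    }
    if (any(band_centers - band_width / 2 <= 0)) {
      stop("band extends to non-positive frequencies")
    }
  } else {
    if (bb_width / 2 >= signal_frequency) {
      stop("broadband masker extends to non-positive frequencies")
    }
  }
  structure(
    list(kind = kind, band_centers = band_centers, band_width = band_width,
         band_level = band_level, bb_width = bb_width, bb_level = bb_level,
         duration = duration, ramp = ramp,
         signal_frequency = signal_frequency,
         share_carrier_phase = share_carrier_phase),
    class = "masker_spec"
  )
}

#' Low-pass noise generated in the frequency domain
#'
#' Builds a buffer of `1/resolution` seconds by assigning independent
#' uniform numbers in \eqn{[-0.5, 0.5]} to the real and imaginary parts of
#' every positive-frequency component up to `cutoff`, with no DC component
#' and nothing above the cutoff, then transforming to the time domain.
#' `fft()` of the result recovers the assigned spectrum exactly.
#'
#' @param cutoff Low-pass cutoff, Hz.
#' @param resolution Frequency resolution, Hz (sets the buffer duration).
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional integer seed for reproducibility.
#' @return Real sample vector of length `sample_rate / resolution`.
#' @export
make_lowpass_noise <- function(cutoff, resolution = 1, sample_rate = 44100,
                               seed = NULL) {
  if (cutoff < resolution) {
    stop("cutoff must be at least the frequency resolution")
  }
  n <- sample_rate / resolution
  if (n != round(n)) {
    stop("resolution must divide the sample rate")
  }
  n <- as.integer(n)
  with_seed(seed, {
    k <- floor(cutoff / resolution) # number of nonzero positive-freq bins
    spec <- complex(real = rep(0, n), imaginary = rep(0, n))
    spec[1 + seq_len(k)] <- complex(
      real = stats::runif(k, -0.5, 0.5),
      imaginary = stats::runif(k, -0.5, 0.5)
    )
    # Hermitian symmetry so the inverse transform is real
    spec[n + 1 - seq_len(k)] <- Conj(spec[1 + seq_len(k)])
    Re(stats::fft(spec, inverse = TRUE)) / n
  })
}

#' Narrowband noise via carrier multiplication
#'
#' Multiplies a random-phase sinusoidal carrier at `center` Hz with a
#' low-pass noise of cutoff `width / 2`, confining the power to
#' \eqn{[center - width/2, center + width/2]}.
#'
#' @param center Band center frequency, Hz.
#' @param width Band width, Hz.
#' @param comod_noise Optional low-pass modulator to reuse (comodulated
#'   bands); if `NULL` a fresh independent modulator is drawn.
#' @param sample_rate Sampling rate, Hz.
#' @param resolution Frequency resolution for the modulator, Hz.
#' @param carrier_phase Optional carrier phase in radians (drawn uniformly
#'   in \eqn{[0, 2\pi)} when `NULL`).
#' @param seed Optional integer seed.
#' @return Unscaled sample vector over the full noise buffer.
#' @export
make_noise_band <- function(center, width, comod_noise = NULL,
                            sample_rate = 44100, resolution = 1,
                            carrier_phase = NULL, seed = NULL) {
  if (center - width / 2 <= 0) {
    stop("band extends to non-positive frequencies")
  }
  with_seed(seed, {
    if (is.null(comod_noise)) {
      comod_noise <- make_lowpass_noise(width / 2, resolution, sample_rate)
    }
    if (is.null(carrier_phase)) carrier_phase <- stats::runif(1, 0, 2 * pi)
    t <- (seq_along(comod_noise) - 1) / sample_rate
    comod_noise * sin(2 * pi * center * t + carrier_phase)
  })
}

#' Assemble one masker realization
#'
#' Multi-band maskers sum five narrow bands (independent modulators for
#' UN; one shared modulator for CM); the BB masker is a single wide band.
#' Each component is generated on the full noise buffer, shortened to the
#' masker duration, ramped, and scaled so its measured level equals the
#' target exactly.
#'
#' @param spec A [masker_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param cal A [calibration()] object.
#' @param seed Optional integer seed.
#' @return Sample vector of `spec$duration` ms.
#' @export
assemble_masker <- function(spec, sample_rate = 44100, cal = calibration(),
                            seed = NULL) {
  stopifnot(inherits(spec, "masker_spec"))
  n <- ms_to_sample(spec$duration, sample_rate)
  n_ramp <- ms_to_sample(spec$ramp, sample_rate)
  with_seed(seed, {
    shape_band <- function(band, level) {
      band <- band[seq_len(n)]
      band <- band * raised_cosine_envelope(n, n_ramp)
      scale_to_level(band, level, cal)
    }
    if (spec$kind == "BB") {
      band <- make_noise_band(spec$signal_frequency, spec$bb_width,
                              sample_rate = sample_rate)
      return(shape_band(band, spec$bb_level))
    }
    shared <- if (spec$kind == "CM") {
      make_lowpass_noise(spec$band_width / 2, sample_rate = sample_rate)
    } else NULL
    shared_phase <- if (isTRUE(spec$share_carrier_phase)) {
      stats::runif(1, 0, 2 * pi)
    } else NULL
    bands <- lapply(spec$band_centers, function(fc) {
      band <- make_noise_band(fc, spec$band_width, comod_noise = shared,
                              sample_rate = sample_rate,
                              carrier_phase = shared_phase)
      shape_band(band, spec$band_level)
    })
    Reduce(`+`, bands)
  })
}

#' Render the ramped signal tone for both ears
#'
#' Both channels carry the same raised-cosine envelope (the envelope is
#' diotic); the right channel's carrier leads the left by `spec$ipd`
#' degrees. Both channels are scaled by one common factor so the left
#' channel's measured level equals `spec$level` exactly.
#'
#' @param spec A [signal_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param cal A [calibration()] object.
#' @return List with numeric `left` and `right` sample vectors.
#' @export
make_signal <- function(spec, sample_rate = 44100, cal = calibration()) {
  stopifnot(inherits(spec, "signal_spec"))
  n <- ms_to_sample(spec$duration, sample_rate)
  if (is.infinite(spec$level) && spec$level < 0) {
    z <- rep(0, n)
    return(list(left = z, right = z))
  }
  n_ramp <- ms_to_sample(spec$ramp, sample_rate)
  env <- raised_cosine_envelope(n, n_ramp)
  t <- (seq_len(n) - 1) / sample_rate
  phase <- 2 * pi * spec$frequency * t
  ipd_rad <- spec$ipd * pi / 180
  left <- env * sin(phase)
  right <- env * sin(phase + ipd_rad)
  gain <- level_to_rms(spec$level, cal) / sqrt(mean(left^2))
  list(left = left * gain, right = right * gain)
}

#' Assemble one complete trial waveform
#'
#' The masker is presented diotically for its full duration; the signal is
#' added to both channels in the masker's final `signal$duration` ms.
#'
#' @param signal A [signal_spec()].
#' @param masker A [masker_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param cal A [calibration()] object.
#' @param seed Optional integer seed (masker noise is regenerated fresh for
#'   every call, emulating per-interval stimulus generation).
#' @return An object of class `trial_audio`: list with `left`, `right`,
#'   `sample_rate`, `signal_onset` (ms re masker onset), and the two specs.
#' @export
assemble_trial <- function(signal, masker, sample_rate = 44100,
                           cal = calibration(), seed = NULL) {
  stopifnot(inherits(signal, "signal_spec"), inherits(masker, "masker_spec"))
  if (signal$duration > masker$duration) {
    stop("signal duration exceeds masker duration")
  }
  with_seed(seed, {
    m <- assemble_masker(masker, sample_rate, cal)
    s <- make_signal(signal, sample_rate, cal)
    n <- length(m)
    ns <- length(s$left)
    idx <- (n - ns + 1):n
    left <- m
    right <- m
    left[idx] <- left[idx] + s$left
    right[idx] <- right[idx] + s$right
    structure(
      list(left = left, right = right, sample_rate = sample_rate,
           signal_onset = masker$duration - signal$duration,
           signal = signal, masker = masker),
      class = "trial_audio"
    )
  })
}

#' @export
print.trial_audio <- function(x, ...) {
  cat(sprintf(
    "<trial_audio> %s masker + %g Hz tone (IPD %g deg, %s dB SPL)\n",
    x$masker$kind, x$signal$frequency, x$signal$ipd,
    format(x$signal$level)
  ))
  cat(sprintf("  %d samples/channel @ %d Hz, signal onset %g ms\n",
              length(x$left), x$sample_rate, x$signal_onset))
  invisible(x)
}

#' Turn a trial waveform into a long tibble
#'
#' @param x A `trial_audio` object.
#' @param ... Unused.
#' @return Tibble with columns `time_ms`, `channel`, `amplitude`.
#' @exportS3Method generics::tidy
tidy.trial_audio <- function(x, ...) {
  t_ms <- (seq_along(x$left) - 1) / x$sample_rate * 1000
  dplyr::bind_rows(
    tibble::tibble(time_ms = t_ms, channel = "left", amplitude = x$left),
    tibble::tibble(time_ms = t_ms, channel = "right", amplitude = x$right)
  )
}

#' Build the signal/masker specification pair for a named condition
#'
#' @param condition One of [stimulus_conditions()].
#' @param level Signal level, dB SPL.
#' @param ... Passed on to [masker_spec()].
#' @return List with elements `signal` and `masker`.
#' @export
condition_specs <- function(condition, level = 50, ...) {
  condition <- match.arg(condition, stimulus_conditions())
  parts <- strsplit(condition, "_", fixed = TRUE)[[1]]
  list(
    signal = signal_spec(ipd = as.numeric(parts[2]), level = level),
    masker = masker_spec(kind = parts[1], ...)
  )
}
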