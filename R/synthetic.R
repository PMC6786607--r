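# Synthetic-data generators: virtual listener cohorts, multichannel EEG
# sweep sets with known ground truth, and salience rating tables. Every
# generator is seed-deterministic and returns its ground truth so each
# pipeline stage can be validated closed-loop.

# Grand-average masked thresholds (dB SPL) encoded as cohort defaults:
# UN_0 and CM_150 as printed, the others implied by the printed CMR and
# BMLD pattern (BB behaves like UN diotically; BB BMLD ~11.5 dB).
default_t707_grand <- function() {
  c(UN_0 = 48.9, CM_0 = 38.2, BB_0 = 48.9,
    UN_150 = 35.0, CM_150 = 26.7, BB_150 = 37.4)
}

#' Generate a virtual listener cohort
#'
#' Per-listener 70.7%-correct levels are the grand values plus independent
#' Gaussian between-listener offsets per condition.
#'
#' @param n_listeners Number of listeners.
#' @param t707_grand Named numeric: grand-average 70.7% level per
#'   condition, dB SPL.
#' @param between_listener_sd Between-listener threshold spread, dB.
#' @param slope Psychometric spread passed to each listener, dB.
#' @param lapse_rate Lapse probability per listener.
#' @param seed Optional integer seed.
#' @return Tibble of class `cohort` with columns `listener`, `condition`,
#'   `t707`; psychometric parameters are carried as attributes.
#' @export
#' @examples
#' make_cohort(n_listeners = 2, seed = 1)
make_cohort <- function(n_listeners = 8, t707_grand = default_t707_grand(),
                        between_listener_sd = 3, slope = 4,
                        lapse_rate = 0, seed = NULL) {
  stopifnot(n_listeners >= 1, between_listener_sd >= 0)
  with_seed(seed, {
    tbl <- tidyr::expand_grid(
      listener = sprintf("L%02d", seq_len(n_listeners)),
      condition = names(t707_grand)
    )
    tbl$t707 <- unname(t707_grand[tbl$condition]) +
      stats::rnorm(nrow(tbl), 0, between_listener_sd)
    structure(
      tibble::as_tibble(tbl),
      slope = slope, lapse_rate = lapse_rate,
      class = c("cohort", class(tbl))
    )
  })
}

#' Build the simulated listener for one cohort member
#'
#' @param cohort A [make_cohort()] tibble (or a subset of its rows).
#' @param listener Listener id; defaults to the single listener present.
#' @return A [simulated_listener()].
#' @export
cohort_listener <- function(cohort, listener = NULL) {
  if (!is.null(listener)) cohort <- cohort[cohort$listener == listener, ]
  stopifnot(nrow(cohort) >= 1, length(unique(cohort$listener)) == 1)
  simulated_listener(
    stats::setNames(cohort$t707, cohort$condition),
    slope = attr(cohort, "slope") %||% 4,
    lapse_rate = attr(cohort, "lapse_rate") %||% 0
  )
}

#' Generation parameters for synthetic AEP sweeps
#'
#' Each sweep is a masker-onset response plus a change complex at the
#' signal onset (600 ms), both built from Gaussian-windowed deflections,
#' embedded in first-order autoregressive background noise; the change
#' complex grows with sensation level following a saturating law
#' \eqn{A(SL) = A_{max}\, SL / (SL + h)} for \eqn{SL > 0} and vanishes at
#' and below masked threshold.
#'
#' @param masker_n1,masker_p2 Lists `list(latency_ms, amplitude_uv)` for
#'   the masker-onset deflections (latencies re masker onset).
#' @param change_n1,change_p2 Lists `list(latency_ms, amplitude_uv)` for
#'   the change-complex deflections at full saturation (latencies re
#'   signal onset).
#' @param half_saturation_sl Sensation level at which the change complex
#'   reaches half its saturated amplitude, dB.
#' @param bump_sd_ms Gaussian deflection width (one per deflection or a
#'   common value), ms.
#' @param latency_jitter_sd Per-set latency offset spread, ms (a listener
#'   idiosyncrasy; constant within a set).
#' @param noise_rms Background noise RMS per channel, microvolts.
#' @param ar_coef First-order autoregressive coefficient of the noise.
#' @param artifact_rate Probability that a sweep carries a high-amplitude
#'   artifact excursion.
#' @param artifact_amp_uv Artifact excursion amplitude, microvolts.
#' @param drift_uv_per_s Slow linear drift slope spread, microvolts per
#'   second (drawn per sweep, zero-mean).
#' @param channel_gains Per-channel template gain; the first channel is
#'   the analysis channel at gain 1.
#' @return An object of class `aep_gen_spec`.
#' @export
aep_gen_spec <- function(masker_n1 = list(latency_ms = 100,
                                          amplitude_uv = -4),
                         masker_p2 = list(latency_ms = 200,
                                          amplitude_uv = 5),
                         change_n1 = list(latency_ms = 130,
                                          amplitude_uv = -5),
                         change_p2 = list(latency_ms = 230,
                                          amplitude_uv = 6),
                         half_saturation_sl = 10,
                         bump_sd_ms = c(20, 25),
                         latency_jitter_sd = 0,
                         noise_rms = 15, ar_coef = 0.95,
                         artifact_rate = 0, artifact_amp_uv = 200,
                         drift_uv_per_s = 0,
                         channel_gains = c(1, 0.6, 0.3)) {
  stopifnot(artifact_rate >= 0, artifact_rate <= 0.2,
            abs(ar_coef) < 1, noise_rms >= 0)
  if (length(bump_sd_ms) == 1) bump_sd_ms <- rep(bump_sd_ms, 2)
  structure(
    list(masker_n1 = masker_n1, masker_p2 = masker_p2,
         change_n1 = change_n1, change_p2 = change_p2,
         half_saturation_sl = half_saturation_sl,
         bump_sd_ms = bump_sd_ms,
         latency_jitter_sd = latency_jitter_sd,
         noise_rms = noise_rms, ar_coef = ar_coef,
         artifact_rate = artifact_rate,
         artifact_amp_uv = artifact_amp_uv,
         drift_uv_per_s = drift_uv_per_s,
         channel_gains = channel_gains),
    class = "aep_gen_spec"
  )
}

# Saturating amplitude growth with sensation level.
amplitude_law <- function(sl, half_saturation_sl = 10) {
  ifelse(sl > 0, sl / (sl + half_saturation_sl), 0)
}

gaussian_bump <- function(t_ms, latency_ms, sd_ms) {
  exp(-(t_ms - latency_ms)^2 / (2 * sd_ms^2))
}

# AR(1) noise scaled to an exact stationary RMS.
ar1_noise <- function(n, coef, rms) {
  if (rms == 0) return(numeric(n))
  innov_sd <- rms * sqrt(1 - coef^2)
  as.vector(stats::filter(stats::rnorm(n, 0, innov_sd), coef,
                          method = "recursive"))
}

#' Generate synthetic epoched EEG sweeps with ground truth
#'
#' @param condition Condition label attached to the sweeps.
#' @param sensation_level Signal level above masked threshold, dB SL
#'   (`-Inf` for a masker-alone set).
#' @param n_sweeps Number of sweeps.
#' @param spec An [aep_gen_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param window_ms Epoch window re masker onset, ms.
#' @param signal_onset_ms Signal onset within the masker, ms.
#' @param seed Optional integer seed.
#' @return List with `sweeps` (a [sweep_set()]) and `truth`: the exact
#'   template peak latencies/amplitudes (re signal onset), the per-sweep
#'   artifact flags and the scale factor applied by the amplitude law.
#' @export
make_sweeps <- function(condition = "CM_0", sensation_level = 20,
                        n_sweeps = 400, spec = aep_gen_spec(),
                        sample_rate = 1024, window_ms = c(-150, 1050),
                        signal_onset_ms = 600, seed = NULL) {
  with_seed(seed, {
    off <- ms_window_to_offsets(window_ms, sample_rate)
    t_ms <- seq(off[1], off[2]) / sample_rate * 1000
    n_t <- length(t_ms)
    n_ch <- length(spec$channel_gains)
    jit <- if (spec$latency_jitter_sd > 0) {
      stats::rnorm(1, 0, spec$latency_jitter_sd)
    } else 0
    scale <- amplitude_law(sensation_level, spec$half_saturation_sl)
    template <-
      spec$masker_n1$amplitude_uv *
        gaussian_bump(t_ms, spec$masker_n1$latency_ms, spec$bump_sd_ms[1]) +
      spec$masker_p2$amplitude_uv *
        gaussian_bump(t_ms, spec$masker_p2$latency_ms, spec$bump_sd_ms[2]) +
      scale * spec$change_n1$amplitude_uv *
        gaussian_bump(t_ms, signal_onset_ms + spec$change_n1$latency_ms +
                        jit, spec$bump_sd_ms[1]) +
      scale * spec$change_p2$amplitude_uv *
        gaussian_bump(t_ms, signal_onset_ms + spec$change_p2$latency_ms +
                        jit, spec$bump_sd_ms[2])
    data <- array(0, dim = c(n_ch, n_t, n_sweeps))
    artifact <- stats::runif(n_sweeps) < spec$artifact_rate
    for (i in seq_len(n_sweeps)) {
      m <- outer(spec$channel_gains, template)
      for (ch in seq_len(n_ch)) {
        m[ch, ] <- m[ch, ] + ar1_noise(n_t, spec$ar_coef, spec$noise_rms)
      }
      if (spec$drift_uv_per_s > 0) {
        m <- m + outer(stats::rnorm(n_ch, 0, spec$drift_uv_per_s),
                       t_ms / 1000)
      }
      if (artifact[i]) {
        ch <- sample.int(n_ch, 1)
        at <- stats::runif(1, t_ms[1] + 50, t_ms[n_t] - 50)
        m[ch, ] <- m[ch, ] + spec$artifact_amp_uv *
          sign(stats::runif(1) - 0.5) * gaussian_bump(t_ms, at, 30)
      }
      data[, , i] <- m
    }
    sweeps <- sweep_set(
      data, sample_rate, window_ms,
      labels = tibble::tibble(condition = rep(condition, n_sweeps),
                              level = rep(sensation_level, n_sweeps)),
      channel_names = c("Cz", if (n_ch > 1) paste0("ch", seq_len(n_ch - 1))),
      analysis_channel = "Cz"
    )
    truth <- list(
      condition = condition, sensation_level = sensation_level,
      scale = scale,
      n1_lat = spec$change_n1$latency_ms + jit,
      n1_amp = scale * spec$change_n1$amplitude_uv,
      p2_lat = spec$change_p2$latency_ms + jit,
      p2_amp = scale * spec$change_p2$amplitude_uv,
      masker_n1 = spec$masker_n1, masker_p2 = spec$masker_p2,
      artifact = artifact
    )
    list(sweeps = sweeps, truth = truth)
  })
}

#' Rating-generation parameters
#'
#' Median salience grows monotonically with sensation level following the
#' same saturating law as the evoked response, scaled to the 0-10
#' endpoint-anchored scale; condition offsets shift whole conditions.
#' `archetype = "SL-ordered"` uses zero offsets (ratings governed by
#' sensation level alone); `"SMR-ordered"` derives offsets from the
#' conditions' masked thresholds so that, at equal sensation level,
#' conditions with higher physical signal-to-masker ratio are rated
#' higher.
#'
#' @param archetype `"SL-ordered"` or `"SMR-ordered"`.
#' @param condition_offsets Named numeric, rating units; overrides the
#'   archetype-derived offsets when given.
#' @param growth_max Saturated median rating for zero offset.
#' @param half_saturation_sl Sensation level of half-saturation, dB.
#' @param rating_noise_sd Within-cell rating spread.
#' @param smr_gain Rating units per dB of threshold difference
#'   (SMR-ordered archetype).
#' @return An object of class `rating_gen_spec`.
#' @export
rating_gen_spec <- function(archetype = c("SL-ordered", "SMR-ordered"),
                            condition_offsets = NULL, growth_max = 9,
                            half_saturation_sl = 10, rating_noise_sd = 1,
                            smr_gain = 0.15) {
  archetype <- match.arg(archetype)
  structure(
    list(archetype = archetype, condition_offsets = condition_offsets,
         growth_max = growth_max, half_saturation_sl = half_saturation_sl,
         rating_noise_sd = rating_noise_sd, smr_gain = smr_gain),
    class = "rating_gen_spec"
  )
}

#' Generate a salience rating table for a cohort
#'
#' One rating per listener, condition, sensation level and block, on the
#' 0-10 endpoint-anchored scale ('not audible' ... 'reference'). Expected
#' ratings are monotone in sensation level and concentrate near zero below
#' masked threshold.
#'
#' @param cohort A [make_cohort()] tibble (supplies listener ids,
#'   conditions and thresholds for the SMR-ordered archetype).
#' @param spec A [rating_gen_spec()].
#' @param levels Sensation levels re individual masked threshold, dB SL.
#' @param n_blocks Rating blocks per cell (post-training).
#' @param seed Optional integer seed.
#' @return Tibble of class `rating_table` with columns `listener`,
#'   `condition`, `level_db_sl`, `block`, `rating`, plus a `truth`
#'   attribute with the configured median surface.
#' @export
make_ratings <- function(cohort, spec = rating_gen_spec(),
                         levels = c(-10, 0, 5, 10, 15, 20),
                         n_blocks = 15, seed = NULL) {
  with_seed(seed, {
    conditions <- unique(cohort$condition)
    offsets <- spec$condition_offsets
    if (is.null(offsets)) {
      offsets <- if (spec$archetype == "SMR-ordered") {
        thr <- tapply(cohort$t707, cohort$condition, mean)[conditions]
        spec$smr_gain * (thr - mean(thr))
      } else {
        stats::setNames(rep(0, length(conditions)), conditions)
      }
    }
    grid <- tidyr::expand_grid(
      listener = unique(cohort$listener),
      condition = conditions,
      level_db_sl = levels,
      block = seq_len(n_blocks)
    )
    target <- spec$growth_max *
      amplitude_law(grid$level_db_sl, spec$half_saturation_sl) +
      offsets[grid$condition]
    rating <- target + stats::rnorm(nrow(grid), 0, spec$rating_noise_sd)
    grid$rating <- pmin(pmax(rating, 0), 10)
    truth <- tibble::tibble(
      condition = rep(conditions, each = length(levels)),
      level_db_sl = rep(levels, times = length(conditions))
    )
    truth$median_target <- pmin(pmax(
      spec$growth_max *
        amplitude_law(truth$level_db_sl, spec$half_saturation_sl) +
        offsets[truth$condition], 0), 10)
    structure(
      tibble::as_tibble(grid),
      truth = truth, offsets = offsets,
      class = c("rating_table", class(grid))
    )
  })
}
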