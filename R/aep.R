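# Auditory evoked potential (AEP) processing chain: epoching, linear
# detrending, zero-phase low-pass filtering, baseline correction, artifact
# rejection, iterative inverse-noise-power weighted averaging, extraction
# of the change complex following the signal onset within the ongoing
# masker, and N1/P2 peak scanning.
#
# Timing skeleton: masker onset at 0 ms, signal onset at 600 ms, epochs
# span [-150, 1050) ms at 1024 Hz.

#' Construct a set of epoched EEG sweeps
#'
#' @param data Numeric array `channel x time x sweep`, in microvolts.
#' @param sample_rate Sampling rate, Hz.
#' @param window_ms Epoch window relative to stimulus (masker) onset, ms;
#'   half-open on the right.
#' @param labels Tibble with one row per sweep (e.g. `condition`,
#'   `level`); `NULL` for unlabeled sweeps.
#' @param channel_names Channel names; must include the analysis channel.
#' @param analysis_channel Channel used for noise estimation and peak
#'   scanning (vertex electrode).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(data, sample_rate = 1024, window_ms = c(-150, 1050),
                      labels = NULL, channel_names = NULL,
                      analysis_channel = "Cz") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(dimnames(data)[[1]])) {
      dimnames(data)[[1]]
    } else if (dim(data)[1] == 1) "Cz" else {
      c("Cz", paste0("ch", seq_len(dim(data)[1] - 1)))
    }
  }
  stopifnot(length(channel_names) == dim(data)[1],
            analysis_channel %in% channel_names)
  if (!is.null(labels)) stopifnot(nrow(labels) == dim(data)[3])
  dimnames(data)[[1]] <- channel_names
  structure(
    list(data = data, sample_rate = sample_rate, window_ms = window_ms,
         labels = labels, channel_names = channel_names,
         analysis_channel = analysis_channel),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sweep_set> %d channel(s) x %d samples x %d sweep(s) @ %g Hz, window [%g, %g) ms\n",
    d[1], d[2], d[3], x$sample_rate, x$window_ms[1], x$window_ms[2]
  ))
  invisible(x)
}

#' Number of sweeps in a sweep set
#' @param x A `sweep_set`.
#' @return Integer sweep count.
#' @export
n_sweeps <- function(x) dim(x$data)[3]

# Epoch time axis in ms (relative to stimulus onset).
sweep_times <- function(x) {
  off <- ms_window_to_offsets(x$window_ms, x$sample_rate)
  seq(off[1], off[2]) / x$sample_rate * 1000
}

subset_sweeps <- function(x, idx) {
  sweep_set(
    x$data[, , idx, drop = FALSE], x$sample_rate, x$window_ms,
    if (!is.null(x$labels)) x$labels[idx, , drop = FALSE] else NULL,
    x$channel_names, x$analysis_channel
  )
}

#' Long-format view of epoched sweeps
#'
#' @param x A `sweep_set`.
#' @param ... Unused.
#' @return Tibble with columns `sweep`, `channel`, `time_ms`, `amplitude`.
#' @exportS3Method generics::tidy
tidy.sweep_set <- function(x, ...) {
  d <- dim(x$data)
  t_ms <- sweep_times(x)
  tibble::tibble(
    sweep = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(x$channel_names, times = d[2] * d[3]),
    time_ms = rep(rep(t_ms, each = d[1]), times = d[3]),
    amplitude = as.vector(x$data)
  )
}

#' Epoch a continuous multichannel record
#'
#' Cuts one sweep per stimulus onset over a half-open window; onsets too
#' close to the record edges are skipped with a warning.
#'
#' @param continuous Numeric matrix `channel x time`, microvolts.
#' @param onsets_ms Stimulus onset times, ms from record start.
#' @param window_ms Epoch window relative to each onset, ms.
#' @param sample_rate Sampling rate, Hz.
#' @param labels Optional tibble with one row per onset.
#' @inheritParams sweep_set
#' @return A [sweep_set()].
#' @export
epoch <- function(continuous, onsets_ms, window_ms = c(-150, 1050),
                  sample_rate = 1024, labels = NULL, channel_names = NULL,
                  analysis_channel = "Cz") {
  if (is.vector(continuous)) continuous <- matrix(continuous, nrow = 1)
  off <- ms_window_to_offsets(window_ms, sample_rate)
  n_t <- off[2] - off[1] + 1
  onset_idx <- ms_to_sample(onsets_ms, sample_rate) + 1L # 1-based
  lo <- onset_idx + off[1]
  hi <- onset_idx + off[2]
  ok <- lo >= 1 & hi <= ncol(continuous)
  if (any(!ok)) {
    warning(sum(!ok), " onset(s) too close to the record edge skipped")
  }
  if (!any(ok)) stop("no onset leaves room for a full epoch")
  keep <- which(ok)
  data <- array(0, dim = c(nrow(continuous), n_t, length(keep)))
  for (i in seq_along(keep)) {
    data[, , i] <- continuous[, lo[keep[i]]:hi[keep[i]], drop = FALSE]
  }
  sweep_set(
    data, sample_rate, window_ms,
    if (!is.null(labels)) labels[keep, , drop = FALSE] else NULL,
    channel_names, analysis_channel
  )
}

# Apply f(channel x time matrix) -> matrix to every sweep.
map_sweeps <- function(x, f) {
  n_ch <- dim(x$data)[1]
  for (i in seq_len(n_sweeps(x))) {
    x$data[, , i] <- f(matrix(x$data[, , i], nrow = n_ch))
  }
  x
}

#' Remove slow linear drift from each sweep
#'
#' Fits a least-squares line on the union of the two fit windows only
#' (by default the 150 ms before the signal onset and the 150 ms after the
#' stimulus ends) and subtracts it from the entire sweep, per channel.
#'
#' @param x A [sweep_set()].
#' @param fit_windows List of two ms windows (relative to masker onset)
#'   defining the samples entering the fit.
#' @return The detrended `sweep_set`.
#' @export
detrend_linear <- function(x,
                           fit_windows = list(c(450, 600), c(900, 1050))) {
  t_ms <- sweep_times(x)
  mask <- Reduce(`|`, lapply(fit_windows, window_mask, times_ms = t_ms))
  if (!any(mask)) stop("fit windows contain no samples")
  X <- cbind(1, t_ms)
  Xw <- X[mask, , drop = FALSE]
  # hat matrix applied to full time axis: predict from windowed fit
  proj <- X %*% solve(crossprod(Xw), t(Xw))
  map_sweeps(x, function(m) m - t(proj %*% t(m[, mask, drop = FALSE])))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (`signal::filtfilt`), doubling the effective order and cancelling the
#' phase response; DC gain is 1.
#'
#' @param x A [sweep_set()].
#' @param cutoff Cut-off frequency, Hz.
#' @param order Filter order (per direction).
#' @return The filtered `sweep_set`.
#' @export
lowpass_zero_phase <- function(x, cutoff = 20, order = 2) {
  stopifnot(cutoff < x$sample_rate / 2)
  bf <- signal::butter(order, cutoff / (x$sample_rate / 2), type = "low")
  map_sweeps(x, function(m) {
    t(apply(m, 1, function(row) signal::filtfilt(bf, row)))
  })
}

#' Baseline-correct each sweep
#'
#' Subtracts the per-channel arithmetic mean over the baseline window
#' (default: the 150 ms pre-stimulus period).
#'
#' @param x A [sweep_set()].
#' @param window_ms Baseline window relative to masker onset, ms.
#' @return The corrected `sweep_set`.
#' @export
baseline_correct <- function(x, window_ms = c(-150, 0)) {
  mask <- window_mask(sweep_times(x), window_ms)
  if (!any(mask)) stop("baseline window contains no samples")
  map_sweeps(x, function(m) {
    m - rowMeans(m[, mask, drop = FALSE])
  })
}

#' Discard sweeps exceeding the artifact rejection threshold
#'
#' A sweep is rejected iff any sample in any recorded channel exceeds the
#' threshold in magnitude (strictly; a sample at exactly the threshold is
#' kept).
#'
#' @param x A [sweep_set()].
#' @param threshold Rejection threshold, microvolts.
#' @return List with `accepted` and `rejected` sweep sets, the rejected
#'   indices, and counts `n_accepted` / `n_rejected`.
#' @export
reject_artifacts <- function(x, threshold = 100) {
  stopifnot(threshold > 0)
  bad <- apply(abs(x$data) > threshold, 3, any)
  if (all(bad)) {
    cond <- if (!is.null(x$labels) && "condition" %in% names(x$labels)) {
      paste(unique(x$labels$condition), collapse = ", ")
    } else "unlabeled"
    stop("all sweeps rejected at +-", threshold, " uV (condition: ",
         cond, ")")
  }
  list(
    accepted = subset_sweeps(x, which(!bad)),
    rejected = if (any(bad)) subset_sweeps(x, which(bad)) else NULL,
    rejected_idx = which(bad),
    n_accepted = sum(!bad), n_rejected = sum(bad)
  )
}

#' Iterative inverse-noise-power weighted average
#'
#' Starting from the arithmetic mean, each sweep's noise power is
#' estimated as the variance of its residual from the current average on
#' the analysis channel; weights proportional to inverse noise power give
#' the next weighted mean, iterated to a fixed point. Sweeps with
#' (near-)zero residual variance trigger a uniform-weight fallback.
#'
#' @param x A [sweep_set()] of accepted sweeps.
#' @param tol Convergence tolerance on the relative change of the average.
#' @param max_iter Iteration cap.
#' @return An object of class `averaged_aep` with the averaged waveform
#'   (`channel x time`), the converged per-sweep weights (summing to 1)
#'   and iteration diagnostics.
#' @export
weighted_average <- function(x, tol = 1e-6, max_iter = 50) {
  ns <- n_sweeps(x)
  if (ns < 2) stop("at least two accepted sweeps are required")
  ch <- match(x$analysis_channel, x$channel_names)
  flat <- matrix(x$data, nrow = prod(dim(x$data)[1:2]), ncol = ns)
  az <- matrix(x$data[ch, , , drop = TRUE], ncol = ns)
  w <- rep(1 / ns, ns)
  avg <- as.vector(flat %*% w)
  avg_a <- as.vector(az %*% w)
  n_iter <- 0
  for (it in seq_len(max_iter)) {
    n_iter <- it
    noise <- apply(az - avg_a, 2, stats::var)
    if (any(noise <= .Machine$double.eps)) {
      w_new <- rep(1 / ns, ns)
    } else {
      w_new <- (1 / noise) / sum(1 / noise)
    }
    new_avg <- as.vector(flat %*% w_new)
    delta <- sqrt(mean((new_avg - avg)^2))
    denom <- sqrt(mean(avg^2))
    w <- w_new
    avg <- new_avg
    avg_a <- as.vector(az %*% w)
    if (denom == 0 || delta / denom < tol) break
  }
  waveform <- matrix(avg, nrow = dim(x$data)[1],
                     dimnames = list(x$channel_names, NULL))
  structure(
    list(waveform = waveform, weights = w, n_accepted = ns,
         n_rejected = 0L, n_iter = n_iter,
         sample_rate = x$sample_rate, window_ms = x$window_ms,
         channel_names = x$channel_names,
         analysis_channel = x$analysis_channel),
    class = "averaged_aep"
  )
}

#' @export
print.averaged_aep <- function(x, ...) {
  cat(sprintf(
    "<averaged_aep> %d sweep(s) averaged in %d iteration(s), %d channel(s)\n",
    x$n_accepted, x$n_iter, nrow(x$waveform)
  ))
  invisible(x)
}

#' Long-format averaged waveform
#'
#' @param x An `averaged_aep`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `time_ms`, `amplitude`.
#' @exportS3Method generics::tidy
tidy.averaged_aep <- function(x, ...) {
  off <- ms_window_to_offsets(x$window_ms, x$sample_rate)
  t_ms <- seq(off[1], off[2]) / x$sample_rate * 1000
  tibble::tibble(
    channel = rep(x$channel_names, times = ncol(x$waveform)),
    time_ms = rep(t_ms, each = nrow(x$waveform)),
    amplitude = as.vector(x$waveform)
  )
}

#' Extract the change complex following the signal onset
#'
#' Restricts the averaged AEP to the interval around the signal onset
#' within the masker, re-baselines on the 150 ms preceding the signal
#' onset, and re-expresses latencies relative to the signal onset.
#'
#' @param avg An [weighted_average()] result (or any `averaged_aep`).
#' @param span_ms Extracted absolute interval, ms re masker onset.
#' @param baseline_ms Baseline window, ms re masker onset.
#' @param signal_onset_ms Signal onset, ms re masker onset.
#' @return An object of class `change_complex`; its time axis is in ms
#'   relative to the signal onset.
#' @export
extract_change_complex <- function(avg, span_ms = c(450, 1050),
                                   baseline_ms = c(450, 600),
                                   signal_onset_ms = 600) {
  off <- ms_window_to_offsets(avg$window_ms, avg$sample_rate)
  t_ms <- seq(off[1], off[2]) / avg$sample_rate * 1000
  keep <- window_mask(t_ms, span_ms)
  if (!any(keep)) stop("extraction span outside the epoch")
  wf <- avg$waveform[, keep, drop = FALSE]
  t_keep <- t_ms[keep]
  base <- window_mask(t_keep, baseline_ms)
  if (!any(base)) stop("baseline window outside the extraction span")
  wf <- wf - rowMeans(wf[, base, drop = FALSE])
  structure(
    list(waveform = wf, times_ms = t_keep - signal_onset_ms,
         baseline_ms = baseline_ms - signal_onset_ms,
         sample_rate = avg$sample_rate,
         channel_names = avg$channel_names,
         analysis_channel = avg$analysis_channel),
    class = "change_complex"
  )
}

#' @export
print.change_complex <- function(x, ...) {
  cat(sprintf(
    "<change_complex> %d channel(s), [%g, %g] ms re signal onset\n",
    nrow(x$waveform), min(x$times_ms), max(x$times_ms)
  ))
  invisible(x)
}

#' Long-format change-complex waveform
#'
#' @param x A `change_complex`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `time_ms` (re signal onset),
#'   `amplitude`.
#' @exportS3Method generics::tidy
tidy.change_complex <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_names, times = ncol(x$waveform)),
    time_ms = rep(x$times_ms, each = nrow(x$waveform)),
    amplitude = as.vector(x$waveform)
  )
}

#' Grand mean over individual change complexes
#'
#' Pointwise arithmetic mean across listeners; all inputs must share the
#' same time grid and channel layout.
#'
#' @param ccs List of `change_complex` objects.
#' @return A `change_complex`.
#' @export
grand_mean <- function(ccs) {
  stopifnot(length(ccs) >= 1,
            all(vapply(ccs, inherits, TRUE, "change_complex")))
  ref <- ccs[[1]]
  for (cc in ccs[-1]) {
    stopifnot(isTRUE(all.equal(cc$times_ms, ref$times_ms)),
              identical(cc$channel_names, ref$channel_names))
  }
  ref$waveform <- Reduce(`+`, lapply(ccs, `[[`, "waveform")) / length(ccs)
  ref
}

# Interior extrema of y via first-derivative sign change.
# Returns tibble(index, value, type) with type "min" (- to +) / "max".
find_extrema <- function(y) {
  d <- diff(y)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) {
    return(tibble::tibble(index = integer(0), value = numeric(0),
                          type = character(0)))
  }
  # collapse runs of zero slope onto the last nonzero sign before them
  idx <- integer(0)
  typ <- character(0)
  for (j in seq_len(length(nz) - 1)) {
    a <- nz[j]
    b <- nz[j + 1]
    if (s[a] != s[b]) {
      idx <- c(idx, a + 1L) # sample where the derivative changes sign
      typ <- c(typ, if (s[a] < 0) "min" else "max")
    }
  }
  tibble::tibble(index = idx, value = y[idx], type = typ)
}

#' Scan the change complex for the N1 and P2 peaks
#'
#' N1 is the negative deflection in the 90-190 ms window and P2 the
#' positive deflection in the 180-290 ms window, both relative to the
#' signal onset. A peak is indicated where the first derivative crosses
#' zero with a sign change of the matching curvature inside the window;
#' among multiple candidates the one with the largest magnitude wins. A
#' candidate of the wrong polarity, an empty window, or a non-increasing
#' N1-to-P2 latency order leaves the peak missing and sets the review
#' flag — the machine-readable analogue of manual waveform verification.
#'
#' @param cc A [extract_change_complex()] result.
#' @param channel Channel to scan (default: the analysis channel).
#' @param n1_window,p2_window Search windows, ms re signal onset.
#' @return An object of class `peak_set` with `n1` and `p2`
#'   (each `NULL` or a list with `latency_ms` and `amplitude_uv`) and
#'   `review_flag`.
#' @export
scan_peaks <- function(cc, channel = NULL, n1_window = c(90, 190),
                       p2_window = c(180, 290)) {
  if (is.null(channel)) channel <- cc$analysis_channel
  y <- cc$waveform[match(channel, cc$channel_names), ]
  t_ms <- cc$times_ms
  ext <- find_extrema(y)
  ext$latency <- t_ms[ext$index]
  pick <- function(window, want_type, polarity) {
    cand <- ext[ext$latency >= window[1] & ext$latency <= window[2] &
                  ext$type == want_type, ]
    if (nrow(cand) == 0) return(NULL)
    best <- cand[which.max(abs(cand$value)), ]
    if (polarity * best$value < 0) return(NULL) # wrong polarity
    list(latency_ms = best$latency, amplitude_uv = best$value)
  }
  n1 <- pick(n1_window, "min", -1)
  p2 <- pick(p2_window, "max", +1)
  review <- is.null(n1) || is.null(p2) ||
    (!is.null(n1) && !is.null(p2) && n1$latency_ms >= p2$latency_ms)
  structure(
    list(n1 = n1, p2 = p2, review_flag = review, channel = channel,
         n1_window = n1_window, p2_window = p2_window),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  fmt <- function(p, lab) {
    if (is.null(p)) sprintf("%s: missing", lab)
    else sprintf("%s: %.1f ms, %.2f uV", lab, p$latency_ms, p$amplitude_uv)
  }
  cat(sprintf("<peak_set> %s | %s%s\n", fmt(x$n1, "N1"), fmt(x$p2, "P2"),
              if (x$review_flag) " [requires review]" else ""))
  invisible(x)
}

#' One-row tibble of detected peaks
#'
#' @param x A `peak_set`.
#' @param ... Unused.
#' @return Tibble with `n1_lat`, `n1_amp`, `p2_lat`, `p2_amp`,
#'   `review_flag` (`NA` for missing peaks).
#' @exportS3Method generics::tidy
tidy.peak_set <- function(x, ...) {
  tibble::tibble(
    channel = x$channel,
    n1_lat = if (is.null(x$n1)) NA_real_ else x$n1$latency_ms,
    n1_amp = if (is.null(x$n1)) NA_real_ else x$n1$amplitude_uv,
    p2_lat = if (is.null(x$p2)) NA_real_ else x$p2$latency_ms,
    p2_amp = if (is.null(x$p2)) NA_real_ else x$p2$amplitude_uv,
    review_flag = x$review_flag
  )
}

#' Summarize peak amplitudes by condition and level
#'
#' Aggregates a per-listener peak table into condition-by-level means of
#' N1, P2 and the P2-N1 difference, with standard errors; missing peaks
#' are excluded pairwise and counted.
#'
#' @param peaks Tibble with columns `listener`, `condition`, `level`,
#'   `n1_amp`, `p2_amp` (e.g. row-bound [tidy.peak_set()] outputs).
#' @return Tibble with one row per condition and level.
#' @export
amplitude_table <- function(peaks) {
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  peaks |>
    dplyr::group_by(.data$condition, .data$level) |>
    dplyr::summarise(
      n1_mean = mean(.data$n1_amp, na.rm = TRUE),
      n1_se = se(.data$n1_amp),
      p2_mean = mean(.data$p2_amp, na.rm = TRUE),
      p2_se = se(.data$p2_amp),
      p2_minus_n1_mean = mean(.data$p2_amp - .data$n1_amp, na.rm = TRUE),
      p2_minus_n1_se = se(.data$p2_amp - .data$n1_amp),
      n_listeners = dplyr::n(),
      n_missing_n1 = sum(is.na(.data$n1_amp)),
      n_missing_p2 = sum(is.na(.data$p2_amp)),
      .groups = "drop"
    )
}

#' Run the full single-condition AEP chain
#'
#' Convenience wrapper sequencing the canonical order: artifact rejection
#' on the raw epochs (so brief high-amplitude excursions cannot be
#' smoothed below threshold by the filter), then linear detrend,
#' zero-phase low-pass, baseline correction, weighted averaging,
#' change-complex extraction and peak scanning.
#'
#' @param x A [sweep_set()].
#' @param lowpass_hz Low-pass cut-off, Hz.
#' @param reject_uv Artifact rejection threshold, microvolts.
#' @return List with `average` (`averaged_aep`), `change_complex`,
#'   `peaks` (`peak_set`), `n_accepted`, `n_rejected`.
#' @export
process_sweeps <- function(x, lowpass_hz = 20, reject_uv = 100) {
  part <- reject_artifacts(x, threshold = reject_uv)
  filtered <- part$accepted |>
    detrend_linear() |>
    lowpass_zero_phase(cutoff = lowpass_hz) |>
    baseline_correct()
  avg <- weighted_average(filtered)
  avg$n_rejected <- part$n_rejected
  cc <- extract_change_complex(avg)
  list(
    average = avg, change_complex = cc, peaks = scan_peaks(cc),
    n_accepted = part$n_accepted, n_rejected = part$n_rejected
  )
}
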