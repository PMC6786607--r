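# AEP chain: epoching, detrending, filtering, baseline, rejection,
# weighted averaging, change-complex extraction and peak scanning.

test_that("epoching cuts half-open windows on the sample grid", {
  fs <- 1024
  rec <- matrix(stats::rnorm(2 * 8 * fs), nrow = 2)
  ss <- epoch(rec, onsets_ms = c(1000, 3000, 5000), sample_rate = fs)
  expect_equal(dim(ss$data), c(2, 1229, 3)) # ceil(1.2 * 1024) samples
  expect_equal(n_sweeps(ss), 3)

  # an onset whose pre-window runs off the record start is skipped
  expect_warning(
    ss2 <- epoch(rec, onsets_ms = c(0, 3000), sample_rate = fs),
    "skipped"
  )
  expect_equal(n_sweeps(ss2), 1)

  const <- matrix(5, nrow = 1, ncol = 8 * fs)
  ss3 <- epoch(const, onsets_ms = c(2000, 4000), sample_rate = fs)
  expect_true(all(ss3$data == 5))

  expect_error(suppressWarnings(epoch(rec, onsets_ms = 0,
                                      sample_rate = fs)),
               "no onset")
})

test_that("linear detrending removes exactly the windowed fit", {
  t_ms <- epoch_times()
  line <- 2 + 0.01 * t_ms
  ss <- as_sweeps(line)
  out <- detrend_linear(ss)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-9)

  # a pulse confined to the masked-out interval survives untouched
  pulse <- 4 * exp(-(t_ms - 750)^2 / (2 * 30^2))
  ss2 <- as_sweeps(line + pulse)
  out2 <- detrend_linear(ss2)
  # oracle: direct least squares on the two fit windows
  mask <- (t_ms >= 450 & t_ms < 600) | (t_ms >= 900 & t_ms < 1050)
  fit <- stats::lm.fit(cbind(1, t_ms[mask]), (line + pulse)[mask])
  oracle <- (line + pulse) - cbind(1, t_ms) %*% fit$coefficients
  expect_equal(as.vector(out2$data[1, , 1]), as.vector(oracle),
               tolerance = 1e-8)

  expect_equal(detrend_linear(as_sweeps(0 * t_ms))$data,
               as_sweeps(0 * t_ms)$data)
})

test_that("the zero-phase low-pass passes 5 Hz and rejects 100 Hz", {
  t_ms <- epoch_times()
  t_s <- t_ms / 1000
  pass <- sin(2 * pi * 5 * t_s)
  out <- lowpass_zero_phase(as_sweeps(pass))$data[1, , 1]
  mid <- seq(300, length(t_s) - 300)
  # amplitude preserved within 2% in the passband
  expect_equal(max(abs(out[mid])), 1, tolerance = 0.02)
  # zero phase: cross-correlation peaks at zero lag
  cc <- stats::ccf(out[mid], pass[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  stopband <- sin(2 * pi * 100 * t_s)
  att <- lowpass_zero_phase(as_sweeps(stopband))$data[1, mid, 1]
  gain_db <- 20 * log10(max(abs(att)))
  expect_lt(gain_db, -20)
  # oracle: forward-backward squares the 2nd-order Butterworth magnitude,
  # |H|^2 = 1/(1 + (f/fc)^4) at f = 5 fc -> about -56 dB
  expect_lt(gain_db, 2 * 10 * log10(1 / (1 + 5^4)) + 6)

  # symmetric pulse keeps its peak latency (+- 1 sample)
  pulse <- exp(-(t_ms - 400)^2 / (2 * 40^2))
  outp <- lowpass_zero_phase(as_sweeps(pulse))$data[1, , 1]
  expect_lte(abs(which.max(outp) - which.max(pulse)), 1)
})

test_that("baseline correction zeroes the window mean per channel", {
  t_ms <- epoch_times()
  ss <- as_sweeps(rbind(rep(5, length(t_ms)), sin(2 * pi * t_ms / 170)))
  out <- baseline_correct(ss, window_ms = c(-150, 0))
  mask <- t_ms >= -150 & t_ms < 0
  expect_equal(mean(out$data[1, mask, 1]), 0, tolerance = 1e-12)
  expect_equal(mean(out$data[2, mask, 1]), 0, tolerance = 1e-12)
  expect_true(all(out$data[1, , 1] == 0)) # constant channel becomes zero
  # sinusoid is shifted by exactly its window mean (direct oracle)
  m <- mean(ss$data[2, mask, 1])
  expect_equal(out$data[2, , 1], ss$data[2, , 1] - m)
})

test_that("artifact rejection uses a strict threshold over all channels", {
  t_ms <- epoch_times()
  n <- length(t_ms)
  clean <- rbind(stats::rnorm(n, sd = 5), stats::rnorm(n, sd = 5))
  spike <- clean
  spike[2, 100] <- 101 # non-analysis channel
  edge <- clean
  edge[1, 50] <- 100 # exactly at threshold: kept
  ss <- as_sweeps(list(clean, spike, edge))
  part <- reject_artifacts(ss, threshold = 100)
  expect_equal(part$rejected_idx, 2L)
  expect_equal(part$n_accepted, 2)

  zeros <- as_sweeps(list(matrix(0, 1, n), matrix(0, 1, n)))
  expect_equal(reject_artifacts(zeros)$n_rejected, 0)

  allbad <- as_sweeps(list(matrix(200, 1, n), matrix(-200, 1, n)))
  expect_error(reject_artifacts(allbad), "all sweeps rejected")
})

test_that("iterative weighting matches inverse-variance algebra", {
  t_ms <- epoch_times()
  n <- length(t_ms)
  template <- 5 * exp(-(t_ms - 730)^2 / (2 * 20^2))

  # equal noise: weights uniform, result equals the arithmetic mean
  set.seed(1)
  eq <- lapply(1:30, function(i) rbind(template + stats::rnorm(n, sd = 3)))
  ss <- as_sweeps(eq)
  avg <- weighted_average(ss)
  expect_equal(sum(avg$weights), 1)
  arith <- apply(ss$data[1, , ], 1, mean)
  expect_lt(sqrt(mean((avg$waveform[1, ] - arith)^2)),
            0.05 * sqrt(mean(arith^2)))
  expect_true(all(avg$weights > 0.5 / 30 & avg$weights < 2 / 30))

  # one 100x-variance sweep among 20 clean ones is down-weighted
  set.seed(2)
  mats <- lapply(1:20, function(i) rbind(template + stats::rnorm(n, 1)))
  mats[[21]] <- rbind(template + stats::rnorm(n, sd = 10))
  avg2 <- weighted_average(as_sweeps(mats))
  expect_lt(avg2$weights[21], 0.02 * mean(avg2$weights[1:20]))
  # oracle: closed-form inverse-variance weights from the known variances
  w_oracle <- c(rep(1, 20), 1 / 100)
  w_oracle <- w_oracle / sum(w_oracle)
  expect_equal(avg2$weights, w_oracle, tolerance = 0.5)
  clean_mean <- apply(simplify2array(mats[1:20]), c(1, 2), mean)[1, ]
  expect_lt(sqrt(mean((avg2$waveform[1, ] - clean_mean)^2)),
            0.05 * sqrt(mean(template^2)))

  # identical sweeps: the fixed point is the common sweep itself
  same <- as_sweeps(list(rbind(template), rbind(template)))
  avg3 <- weighted_average(same)
  expect_equal(avg3$waveform[1, ], template)
  expect_equal(avg3$weights, c(0.5, 0.5))
})

test_that("weighting never degrades the average on heteroscedastic sets", {
  t_ms <- epoch_times()
  n <- length(t_ms)
  template <- -4 * exp(-(t_ms - 730)^2 / (2 * 20^2)) +
    5 * exp(-(t_ms - 830)^2 / (2 * 25^2))
  set.seed(3)
  for (rep in 1:5) {
    sds <- sample(c(2, 5, 15), 40, replace = TRUE)
    mats <- lapply(sds, function(s) rbind(template + stats::rnorm(n, sd = s)))
    ss <- as_sweeps(mats)
    avg <- weighted_average(ss)
    arith <- apply(ss$data[1, , ], 1, mean)
    err_w <- mean((avg$waveform[1, ] - template)^2)
    err_a <- mean((arith - template)^2)
    expect_lte(err_w, err_a)
  }
})

test_that("the averaged waveform is stable under sweep reordering", {
  t_ms <- epoch_times()
  set.seed(4)
  mats <- lapply(1:25, function(i) {
    rbind(exp(-(t_ms - 700)^2 / 800) + stats::rnorm(length(t_ms),
                                                    sd = i / 5))
  })
  a1 <- weighted_average(as_sweeps(mats))
  a2 <- weighted_average(as_sweeps(mats[sample(25)]))
  expect_equal(a1$waveform, a2$waveform, tolerance = 1e-4)
})

test_that("change-complex extraction rebaselines and shifts latencies", {
  t_ms <- epoch_times()
  const <- as_sweeps(list(rbind(t_ms * 0 + 3), rbind(t_ms * 0 + 3)))
  avg <- weighted_average(const)
  cc <- extract_change_complex(avg)
  expect_equal(max(abs(cc$waveform)), 0, tolerance = 1e-12)
  expect_equal(range(cc$times_ms), c(-150, 450), tolerance = 1)

  # deflection injected at 830 ms absolute appears at 230 ms re onset
  bump <- 4 * exp(-(t_ms - 830)^2 / (2 * 20^2))
  avg2 <- weighted_average(as_sweeps(list(rbind(bump), rbind(bump))))
  cc2 <- extract_change_complex(avg2)
  expect_equal(cc2$times_ms[which.max(cc2$waveform[1, ])], 230,
               tolerance = 1)
  base <- cc2$times_ms >= -150 & cc2$times_ms < 0
  expect_equal(mean(cc2$waveform[1, base]), 0, tolerance = 1e-12)
})

test_that("peak scanning finds extrema by derivative sign change", {
  t_ms <- epoch_times()
  g <- function(mu, sd) exp(-(t_ms - (600 + mu))^2 / (2 * sd^2))
  mk_cc <- function(y) {
    avg <- weighted_average(as_sweeps(list(rbind(y), rbind(y))))
    extract_change_complex(avg)
  }
  pk <- scan_peaks(mk_cc(-2 * g(130, 20) + 3 * g(230, 25)), channel = "Cz")
  expect_false(pk$review_flag)
  expect_equal(pk$n1$latency_ms, 130, tolerance = 1.5)
  expect_equal(pk$n1$amplitude_uv, -2, tolerance = 0.05)
  expect_equal(pk$p2$latency_ms, 230, tolerance = 1.5)
  expect_equal(pk$p2$amplitude_uv, 3, tolerance = 0.05)

  # among competing minima the larger magnitude wins
  two <- -1 * g(110, 8) - 3 * g(160, 8) + 2 * g(240, 15)
  pk2 <- scan_peaks(mk_cc(two))
  expect_equal(pk2$n1$latency_ms, 160, tolerance = 2)
  expect_equal(pk2$n1$amplitude_uv, -3, tolerance = 0.1)

  # monotone segment: no extrema, both peaks missing, review flagged
  ramp <- (t_ms - min(t_ms)) / 100
  pk3 <- scan_peaks(mk_cc(ramp))
  expect_null(pk3$n1)
  expect_null(pk3$p2)
  expect_true(pk3$review_flag)

  # wrong polarity inside the N1 window: peak missing, flagged
  pk4 <- scan_peaks(mk_cc(2 * g(140, 15)))
  expect_null(pk4$n1)
  expect_true(pk4$review_flag)
})

test_that("grand means average change complexes pointwise", {
  t_ms <- epoch_times()
  mk_cc <- function(y) {
    extract_change_complex(
      weighted_average(as_sweeps(list(rbind(y), rbind(y))))
    )
  }
  g <- function(mu) -3 * exp(-(t_ms - (600 + mu))^2 / (2 * 18^2))
  one <- mk_cc(g(130))
  expect_equal(grand_mean(list(one))$waveform, one$waveform)
  opp <- mk_cc(-g(130))
  expect_equal(max(abs(grand_mean(list(one, opp))$waveform)), 0,
               tolerance = 1e-9)
  # latency jitter across listeners broadens and shrinks the grand peak
  jittered <- lapply(c(-20, -10, 0, 10, 20), function(j) mk_cc(g(130 + j)))
  gm <- grand_mean(jittered)
  expect_lt(max(abs(gm$waveform)), max(abs(one$waveform)))
})

test_that("amplitude tables aggregate peaks across listeners", {
  peaks <- tibble::tibble(
    listener = c("A", "B", "A", "B"),
    condition = c("CM_0", "CM_0", "UN_0", "UN_0"),
    level = 20,
    n1_amp = c(-2, -3, -1, NA),
    p2_amp = c(3, 4, 2, 2.5)
  )
  tbl <- amplitude_table(peaks)
  cm <- tbl[tbl$condition == "CM_0", ]
  expect_equal(cm$n1_mean, -2.5)
  expect_equal(cm$p2_mean, 3.5)
  expect_equal(cm$p2_minus_n1_mean, 6)
  un <- tbl[tbl$condition == "UN_0", ]
  expect_equal(un$n_missing_n1, 1)
  # single listener with both peaks: table equals that listener's values
  solo <- amplitude_table(peaks[1, ])
  expect_equal(solo$n1_mean, -2)
  expect_equal(solo$p2_minus_n1_mean, 5)
})
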