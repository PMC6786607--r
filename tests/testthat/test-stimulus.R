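# Stimulus synthesis: spectral construction, comodulation, calibration,
# interaural phase and trial assembly.

test_that("frequency-domain low-pass noise has the forced spectral shape", {
  fs <- 1024
  x <- make_lowpass_noise(12, resolution = 1, sample_rate = fs, seed = 1)
  expect_length(x, fs)
  X <- stats::fft(x)
  expect_lt(Mod(X[1]), 1e-10)                      # no DC
  expect_equal(sum(Mod(X[2:(fs / 2)]) > 1e-10), 12) # 12 bins, rest zero
  expect_identical(
    make_lowpass_noise(12, sample_rate = fs, seed = 7),
    make_lowpass_noise(12, sample_rate = fs, seed = 7)
  )
  expect_error(make_lowpass_noise(0.5, resolution = 1),
               "at least the frequency resolution")
})

test_that("mean per-bin spectral power matches the uniform-draw variance", {
  # each complex bin has Re, Im ~ U(-0.5, 0.5): E|X_k|^2 = 2/12 = 1/6
  fs <- 1024
  set.seed(42)
  pows <- replicate(3000, {
    X <- stats::fft(make_lowpass_noise(12, sample_rate = fs))
    mean(Mod(X[2:13])^2)
  })
  expect_equal(mean(pows), 1 / 6, tolerance = 0.02)
})

test_that("narrowband noise is spectrally confined and envelope-coherent", {
  fs <- 4096
  band <- make_noise_band(700, 24, sample_rate = fs, seed = 3)
  expect_gte(band_power_fraction(band, fs, 688, 712), 0.99)

  # shared modulator -> identical demodulated envelopes
  mod <- make_lowpass_noise(12, sample_rate = fs, seed = 5)
  b1 <- make_noise_band(300, 24, comod_noise = mod, sample_rate = fs,
                        seed = 11)
  b2 <- make_noise_band(1100, 24, comod_noise = mod, sample_rate = fs,
                        seed = 12)
  expect_gt(envelope_correlation(b1, b2), 0.99)

  expect_error(make_noise_band(10, 24), "non-positive frequencies")
})

test_that("independent bands have zero expected envelope correlation", {
  fs <- 4096
  set.seed(8)
  cors <- replicate(200, {
    envelope_correlation(
      make_noise_band(300, 24, sample_rate = fs),
      make_noise_band(1000, 24, sample_rate = fs)
    )
  })
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("masker components are calibrated exactly", {
  cal <- calibration(100)
  bb <- assemble_masker(masker_spec("BB"), cal = cal, seed = 2)
  expect_equal(measure_level(bb, cal), 60, tolerance = 1e-8)
  expect_length(bb, ms_to_sample(900, 44100))

  # single signal-centered band renders at the per-band level
  one <- assemble_masker(masker_spec("UN", band_centers = 700), cal = cal,
                         seed = 3)
  expect_equal(measure_level(one, cal), 50, tolerance = 1e-8)

  # five independent equal-level bands add in power: 50 + 10 log10(5)
  un <- assemble_masker(masker_spec("UN"), cal = cal, seed = 4)
  expect_equal(measure_level(un, cal), 50 + 10 * log10(5),
               tolerance = 0.2)

  # measured level of the signal-centered band inside the summed masker
  scb <- fft_bandpass(un, 44100, 680, 720)
  expect_equal(measure_level(scb, cal), 50, tolerance = 0.1)
})

test_that("comodulated masker bands share their intensity fluctuations", {
  fs <- 44100
  cm <- assemble_masker(masker_spec("CM"), sample_rate = fs, seed = 6)
  centers <- c(300, 400, 700, 1000, 1100)
  bands <- lapply(centers, function(fc) {
    fft_bandpass(cm, fs, fc - 20, fc + 20)
  })
  cors <- utils::combn(5, 2, function(ij) {
    envelope_correlation(bands[[ij[1]]], bands[[ij[2]]])
  })
  expect_true(all(cors > 0.95))

  # uncorrelated masker: envelopes unrelated across bands
  un <- assemble_masker(masker_spec("UN"), sample_rate = fs, seed = 7)
  b1 <- fft_bandpass(un, fs, 280, 320)
  b2 <- fft_bandpass(un, fs, 1080, 1120)
  expect_lt(abs(envelope_correlation(b1, b2)), 0.5)
})

test_that("ramps follow the raised-cosine profile and silence the edges", {
  env <- raised_cosine_envelope(1000, 100)
  expect_equal(env[1], 0)
  expect_equal(env[1000], 0)
  expect_true(all(env[101:900] == 1))
  # closed form over the onset ramp
  expect_equal(env[1:100], 0.5 * (1 - cos(pi * (0:99) / 100)))
  # offset ramp mirrors the onset ramp
  expect_equal(env[1000:901], env[1:100])

  m <- assemble_masker(masker_spec("UN"), seed = 9)
  expect_equal(m[1], 0)
  expect_equal(m[length(m)], 0)
  # ramp region carries far less energy than the plateau
  fs <- 44100
  expect_lt(sqrt(mean(m[1:ms_to_sample(2, fs)]^2)),
            0.05 * sqrt(mean(m^2)))
})

test_that("signal rendering honors level, IPD and diotic envelope", {
  s0 <- make_signal(signal_spec(ipd = 0, level = 70))
  expect_identical(s0$left, s0$right)
  expect_equal(measure_level(s0$left), 70, tolerance = 1e-8)

  s360 <- make_signal(signal_spec(ipd = 359.9999, level = 70))
  expect_equal(s360$left, s360$right, tolerance = 1e-4)

  s <- make_signal(signal_spec(ipd = 150, level = 70))
  fs <- 44100
  # steady state: central 200 ms, ramps excluded
  idx <- seq(ms_to_sample(50, fs), ms_to_sample(250, fs))
  n <- length(idx)
  k <- round(700 * n / fs) + 1
  cross <- Conj(stats::fft(s$left[idx])[k]) * stats::fft(s$right[idx])[k]
  expect_equal(Arg(cross) * 180 / pi, 150, tolerance = 0.5)
  # the envelope stays diotic
  expect_equal(analytic_envelope(s$left), analytic_envelope(s$right),
               tolerance = 1e-3)
})

test_that("trial assembly places the signal in the final masker portion", {
  sig <- signal_spec(ipd = 0, level = 60)
  msk <- masker_spec("BB")
  trial <- assemble_trial(sig, msk, seed = 10)
  expect_equal(trial$signal_onset, 600)

  # absent signal: trial is the masker alone in both channels
  silent <- assemble_trial(signal_spec(level = -Inf), msk, seed = 10)
  expect_identical(silent$left, silent$right)
  masker_alone <- assemble_masker(msk, seed = 10)
  expect_equal(silent$left, masker_alone)

  # masker-only segment of a BB trial sits at the nominal masker level
  fs <- 44100
  seg <- trial$left[seq_len(ms_to_sample(600, fs))]
  expect_equal(measure_level(seg), 60, tolerance = 0.2)

  expect_error(
    assemble_trial(signal_spec(duration = 950, level = 50),
                   masker_spec("BB")),
    "exceeds masker duration"
  )

  # identical seeds give bit-identical trials
  t1 <- assemble_trial(sig, msk, seed = 123)
  t2 <- assemble_trial(sig, msk, seed = 123)
  expect_identical(t1$left, t2$left)
  expect_identical(t1$right, t2$right)
})

test_that("level measurement follows the calibration convention", {
  cal <- calibration(100)
  expect_equal(measure_level(rep(1, 64), cal), 100)
  x <- sin(2 * pi * 13 * (0:999) / 1000)
  expect_equal(measure_level(x, cal) - measure_level(x / 2, cal), 6.02,
               tolerance = 0.01)
  # sine of peak 0.1: RMS = 0.1 / sqrt(2)
  expect_equal(measure_level(0.1 * x, cal), 100 + 20 * log10(0.1 / sqrt(2)),
               tolerance = 0.01)
  expect_identical(measure_level(rep(0, 10), cal), -Inf)
})

test_that("WAV files round-trip through the PCM16 writer", {
  trial <- assemble_trial(signal_spec(level = 60), masker_spec("BB"),
                          seed = 5)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(trial$left, trial$right, path, 44100)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100)
  expect_lt(max(abs(back$left - trial$left)), 1 / 32767)
  expect_lt(max(abs(back$right - trial$right)), 1 / 32767)
})
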