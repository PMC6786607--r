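# Experiment orchestration and file-format glue: one configuration tree
# drives stimulus rendering and the three simulated experiments, each
# writing a self-describing output directory (config snapshot, seeds,
# CSV/JSON results). All randomness flows from one global seed through
# named substreams (stimuli, staircase, eeg, ratings), so each experiment
# is independently reproducible.

#' Default run configuration
#'
#' Every field defaults to the design's stated parameter where one exists;
#' the remainder are the package defaults documented on the constructors.
#'
#' @param seed Global seed.
#' @return Nested list of class `run_config` with sections `stimulus`,
#'   `staircase`, `cohort`, `aep`, `ratings`.
#' @export
default_config <- function(seed = 1) {
  structure(
    list(
      seed = as.integer(seed),
      stimulus = list(
        sample_rate = 44100, full_scale_spl = 100,
        signal_frequency = 700, signal_duration = 300, signal_ramp = 20,
        signal_level = 50, masker_duration = 900, masker_ramp = 20,
        band_centers = c(300, 400, 700, 1000, 1100), band_width = 24,
        band_level = 50, bb_width = 824, bb_level = 60,
        share_carrier_phase = FALSE
      ),
      staircase = list(
        initial_step = 8, min_step = 1, reversals_at_min = 6,
        n_intervals = 3, n_down = 2, min_level = -20, max_level = 100,
        max_trials = 200, max_bound_hits = 10, n_runs = 4
      ),
      cohort = list(
        n_listeners = 8, between_listener_sd = 3, slope = 4,
        lapse_rate = 0, t707_grand = as.list(default_t707_grand())
      ),
      aep = list(
        n_sweeps = 400, sensation_levels = c(10, 15, 20, 25),
        sample_rate = 1024, lowpass_hz = 20, reject_uv = 100,
        artifact_rate = 0.05, noise_rms = 15, ar_coef = 0.95
      ),
      ratings = list(
        levels = c(-10, 0, 5, 10, 15, 20), n_blocks = 15,
        archetype = "SL-ordered", rating_noise_sd = 1
      )
    ),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless for every field of [default_config()].
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `write_run_config()`: `path`, invisibly. `read_run_config()`:
#'   the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks that every key of [default_config()] is present; a missing key
#' raises an error naming it.
#'
#' @param config Candidate configuration list.
#' @return The configuration with class `run_config`.
#' @export
validate_config <- function(config) {
  ref <- unclass(default_config())
  if (!"seed" %in% names(config)) stop("missing config key: seed")
  for (sec in setdiff(names(ref), "seed")) {
    if (!sec %in% names(config)) stop("missing config section: ", sec)
    miss <- setdiff(names(ref[[sec]]), names(config[[sec]]))
    if (length(miss)) {
      stop("missing config key: ", sec, "$", miss[1])
    }
  }
  structure(config, class = "run_config")
}

config_calibration <- function(config) {
  calibration(config$stimulus$full_scale_spl)
}

config_masker_spec <- function(config, kind) {
  st <- config$stimulus
  masker_spec(
    kind = kind, band_centers = unlist(st$band_centers),
    band_width = st$band_width, band_level = st$band_level,
    bb_width = st$bb_width, bb_level = st$bb_level,
    duration = st$masker_duration, ramp = st$masker_ramp,
    signal_frequency = st$signal_frequency,
    share_carrier_phase = isTRUE(st$share_carrier_phase)
  )
}

config_signal_spec <- function(config, ipd, level = NULL) {
  st <- config$stimulus
  signal_spec(
    frequency = st$signal_frequency, duration = st$signal_duration,
    ramp = st$signal_ramp, ipd = ipd,
    level = level %||% st$signal_level
  )
}

config_staircase <- function(config) {
  sc <- config$staircase
  staircase_config(
    initial_step = sc$initial_step, min_step = sc$min_step,
    reversals_at_min = sc$reversals_at_min, n_intervals = sc$n_intervals,
    n_down = sc$n_down, min_level = sc$min_level,
    max_level = sc$max_level, max_trials = sc$max_trials,
    max_bound_hits = sc$max_bound_hits
  )
}

config_cohort <- function(config, seed) {
  co <- config$cohort
  make_cohort(
    n_listeners = co$n_listeners,
    t707_grand = unlist(co$t707_grand),
    between_listener_sd = co$between_listener_sd,
    slope = co$slope, lapse_rate = co$lapse_rate, seed = seed
  )
}

prepare_out_dir <- function(out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  out_dir
}

#' Render the six stimulus conditions to WAV files
#'
#' Writes one calibrated stereo WAV per condition plus a JSON manifest
#' recording file names, seeds and measured levels.
#'
#' @param config A [default_config()]-shaped configuration.
#' @param out_dir Output directory (created if needed).
#' @param conditions Conditions to render.
#' @return Manifest tibble (file, condition, seed, measured levels),
#'   invisibly written as `manifest.json`.
#' @export
render_stimuli <- function(config = default_config(), out_dir,
                           conditions = stimulus_conditions()) {
  config <- validate_config(config)
  prepare_out_dir(out_dir, config)
  cal <- config_calibration(config)
  fs <- config$stimulus$sample_rate
  base_seed <- substream_seed(config$seed, "stimuli")
  manifest <- purrr::map_dfr(seq_along(conditions), function(i) {
    cond <- conditions[i]
    parts <- strsplit(cond, "_", fixed = TRUE)[[1]]
    seed <- base_seed + i
    trial <- assemble_trial(
      config_signal_spec(config, ipd = as.numeric(parts[2])),
      config_masker_spec(config, kind = parts[1]),
      sample_rate = fs, cal = cal, seed = seed
    )
    file <- sprintf("%s_level%g_seed%d.wav", cond,
                    config$stimulus$signal_level, seed)
    # headroom: full scale is 100 dB SPL, stimuli stay well below it
    write_wav(trial$left, trial$right, file.path(out_dir, file), fs)
    tibble::tibble(
      file = file, condition = cond, seed = seed,
      signal_level_db_spl = config$stimulus$signal_level,
      measured_level_left = measure_level(trial$left, cal),
      measured_level_right = measure_level(trial$right, cal),
      signal_onset_ms = trial$signal_onset
    )
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}

#' Simulate the threshold experiment end to end
#'
#' Generates a cohort, runs the adaptive staircase for all conditions and
#' listeners, and summarises thresholds, CMR and BMLD. With `out_dir` set,
#' writes `run_thresholds.csv`, `final_thresholds.csv`,
#' `masking_release.csv` and the config snapshot.
#'
#' @param config A run configuration.
#' @param out_dir Optional output directory.
#' @return List with `cohort`, `runs`, `final`, `summary`
#'   (a [masking_release_summary()]).
#' @export
run_experiment1 <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- substream_seed(config$seed, "staircase")
  cohort <- config_cohort(config, seed = seed)
  runs <- simulate_thresholds(
    cohort, config_staircase(config),
    n_runs = config$staircase$n_runs, seed = seed + 1
  )
  final <- final_thresholds(runs)
  summary <- masking_release_summary(final)
  if (!is.null(out_dir)) {
    prepare_out_dir(out_dir, config)
    utils::write.csv(runs, file.path(out_dir, "run_thresholds.csv"),
                     row.names = FALSE)
    utils::write.csv(final, file.path(out_dir, "final_thresholds.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(summary),
                     file.path(out_dir, "masking_release.csv"),
                     row.names = FALSE)
  }
  list(cohort = cohort, runs = runs, final = final, summary = summary)
}

#' Simulate the evoked-potential experiment end to end
#'
#' Generates synthetic sweep sets per condition and sensation level, runs
#' the full AEP chain on each, and collects the peak table. With `out_dir`
#' set, writes `peaks.csv`, per-set averaged waveforms
#' (`avg_<condition>_<level>.csv`) and a processing log with rejection
#' counts.
#'
#' @param config A run configuration.
#' @param out_dir Optional output directory.
#' @param conditions Conditions to simulate.
#' @return List with `peaks` (tidy peak table incl. ground truth columns)
#'   and `results` (per-set pipeline outputs).
#' @export
run_experiment2 <- function(config = default_config(), out_dir = NULL,
                            conditions = stimulus_conditions()) {
  config <- validate_config(config)
  base_seed <- substream_seed(config$seed, "eeg")
  ae <- config$aep
  spec <- aep_gen_spec(noise_rms = ae$noise_rms, ar_coef = ae$ar_coef,
                       artifact_rate = ae$artifact_rate)
  grid <- tidyr::expand_grid(condition = conditions,
                             level = unlist(ae$sensation_levels))
  results <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  if (!is.null(out_dir)) prepare_out_dir(out_dir, config)
  for (i in seq_len(nrow(grid))) {
    gen <- make_sweeps(
      condition = grid$condition[i], sensation_level = grid$level[i],
      n_sweeps = ae$n_sweeps, spec = spec,
      sample_rate = ae$sample_rate, seed = base_seed + i
    )
    res <- process_sweeps(gen$sweeps, lowpass_hz = ae$lowpass_hz,
                          reject_uv = ae$reject_uv)
    results[[i]] <- res
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(condition = grid$condition[i],
                     level_db_sl = grid$level[i],
                     n_accepted = res$n_accepted,
                     n_rejected = res$n_rejected,
                     true_n1_amp = gen$truth$n1_amp,
                     true_p2_amp = gen$truth$p2_amp,
                     true_n1_lat = gen$truth$n1_lat,
                     true_p2_lat = gen$truth$p2_lat),
      tidy(res$peaks)
    )
    if (!is.null(out_dir)) {
      wf <- tidy(res$average) |>
        tidyr::pivot_wider(names_from = "channel",
                           values_from = "amplitude")
      utils::write.csv(
        wf, file.path(out_dir, sprintf("avg_%s_%g.csv", grid$condition[i],
                                       grid$level[i])),
        row.names = FALSE
      )
    }
  }
  peaks <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    utils::write.csv(peaks, file.path(out_dir, "peaks.csv"),
                     row.names = FALSE)
  }
  list(peaks = peaks, results = results)
}

#' Simulate the salience-rating experiment end to end
#'
#' Generates a rating table for the configured cohort, aggregates medians
#' and interquartile ranges, and runs the level-effect and
#' condition-effect Friedman tests. With `out_dir` set, writes
#' `ratings.csv`, `medians.csv` and `friedman.json`.
#'
#' @param config A run configuration.
#' @param out_dir Optional output directory.
#' @return List with `ratings`, `medians`, `grand_matrix`, `tests`.
#' @export
run_experiment3 <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- substream_seed(config$seed, "ratings")
  cohort <- config_cohort(config, seed = seed)
  rt <- config$ratings
  ratings <- make_ratings(
    cohort,
    rating_gen_spec(archetype = rt$archetype,
                    rating_noise_sd = rt$rating_noise_sd),
    levels = unlist(rt$levels), n_blocks = rt$n_blocks, seed = seed + 1
  )
  medians <- aggregate_ratings(ratings)
  tests <- run_experiment3_tests(ratings)
  if (!is.null(out_dir)) {
    prepare_out_dir(out_dir, config)
    utils::write.csv(ratings, file.path(out_dir, "ratings.csv"),
                     row.names = FALSE)
    utils::write.csv(medians, file.path(out_dir, "medians.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      tidy(tests), file.path(out_dir, "friedman.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(ratings = ratings, medians = medians,
       grand_matrix = grand_median_matrix(ratings), tests = tests)
}
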