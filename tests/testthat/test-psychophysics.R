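# Adaptive staircase: psychometric model, track dynamics, threshold
# estimation and the CMR/BMLD arithmetic.

test_that("the logistic observer saturates correctly and hits 70.7%", {
  li <- simulated_listener(c(A = 50), slope = 4)
  expect_equal(p_correct(li, "A", 1e6), 1)
  expect_equal(p_correct(li, "A", -1e6), 1 / 3)
  expect_equal(p_correct(li, "A", 50), 0.707)

  # with a lapse rate the defining constraint still holds exactly
  li2 <- simulated_listener(c(A = 50), slope = 4, lapse_rate = 0.02)
  expect_equal(p_correct(li2, "A", 50), 0.707)
  expect_equal(p_correct(li2, "A", 1e6), 1 - 0.02)

  set.seed(1)
  hits <- sum(stats::runif(1e5) < p_correct(li, "A", 50))
  expect_equal(hits / 1e5, 0.707, tolerance = 0.005 / 0.707)

  expect_error(p_correct(li, "missing", 50), "not configured")
})

test_that("a step-function observer pins the track at its edge", {
  # always correct above 40 dB, always wrong at or below
  oracle <- function(condition, level) level > 40
  tr <- run_track(oracle, cfg = staircase_config(start_level = 60),
                  seed = 1)
  expect_true(tr$converged)
  expect_gte(tr$threshold, 40)
  expect_lte(tr$threshold, 41)
})

test_that("an always-correct observer is flagged non-converged", {
  tr <- run_track(function(condition, level) TRUE,
                  cfg = staircase_config(start_level = 50))
  expect_false(tr$converged)
  expect_true(is.na(tr$threshold))
  expect_gt(tr$bound_hits, 0)
  expect_equal(min(tidy(tr)$level), staircase_config()$min_level)
})

test_that("the one-up two-down track converges to the 70.7% point", {
  li <- simulated_listener(c(A = 48.9), slope = 4)
  set.seed(7)
  thr <- replicate(500, run_track(li, "A")$threshold)
  expect_true(all(!is.na(thr)))
  expect_lt(abs(mean(thr) - 48.9), 0.5)
})

test_that("step sizes halve at lower reversals and floor at the minimum", {
  li <- simulated_listener(c(A = 40), slope = 4)
  for (seed in 1:20) {
    tr <- run_track(li, "A", seed = seed)
    log <- tidy(tr)
    # non-increasing step sequence, never below the minimum
    expect_true(all(diff(log$step) <= 0))
    expect_true(all(log$step >= tr$config$min_step))
    # the distinct step plateaus are the halving schedule 8, 4, 2, 1
    expect_true(all(unique(log$step) %in% c(8, 4, 2, 1)))
    # the step recorded at each lower reversal halves (until the floor)
    low <- tr$reversals$step[tr$reversals$type == "lower"]
    low <- low[low > tr$config$min_step]
    if (length(low) > 1) expect_equal(low[-1], low[-length(low)] / 2)
    # reversal bookkeeping: logged flags match the reversal table
    expect_equal(which(log$reversal), tr$reversals$trial)
    # threshold uses exactly the min-step reversals
    at_min <- tr$reversals$level[tr$reversals$step <= tr$config$min_step]
    expect_length(at_min, tr$config$reversals_at_min)
    expect_equal(tr$threshold, mean(at_min))
    # reversal types strictly alternate
    expect_true(all(tr$reversals$type[-1] !=
                      tr$reversals$type[-nrow(tr$reversals)]))
  }
})

test_that("final thresholds discard the first run and average the rest", {
  est <- estimate_final_threshold(c(50, 48, 49, 47))
  expect_equal(est$final, 48)
  expect_equal(estimate_final_threshold(c(40, 40, 40, 40))$final, 40)
  expect_equal(estimate_final_threshold(c(60, 48.9, 49.1, 49.0))$final, 49)
  expect_error(estimate_final_threshold(c(50, 48, 49)), "at least four")
  expect_error(
    estimate_final_threshold(c(50, 48, NA, 47),
                             converged = c(TRUE, TRUE, FALSE, TRUE)),
    "rerun"
  )
  # the practice run may be non-converged
  est2 <- estimate_final_threshold(c(NA, 48, 49, 47),
                                   converged = c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(est2$final, 48)
})

test_that("CMR and BMLD are exact threshold differences", {
  expect_equal(compute_cmr(48.9, 38.2), 10.7)
  expect_equal(compute_cmr(40, 40), 0)
  expect_equal(compute_cmr(40, 45), -5)
  expect_equal(compute_bmld(48.9, 35.0), 13.9)
  expect_equal(compute_bmld(30, 20), 10)
})

test_that("a null listener configuration yields zero CMR and BMLD", {
  t707 <- stats::setNames(rep(42, 6), stimulus_conditions())
  cohort <- make_cohort(n_listeners = 1, t707_grand = t707,
                        between_listener_sd = 0, seed = 1)
  set.seed(2)
  reps <- purrr::map_dfr(1:60, function(i) {
    runs <- simulate_thresholds(cohort, n_runs = 4)
    tidy(masking_release_summary(final_thresholds(runs)))
  })
  effects <- reps |>
    dplyr::filter(grepl("^cmr|^bmld", .data$measure)) |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(bias = mean(.data$value))
  expect_true(all(abs(effects$bias) < 0.5))
})

test_that("the full threshold experiment recovers configured listeners", {
  cohort <- make_cohort(n_listeners = 2, between_listener_sd = 0, seed = 3)
  runs <- simulate_thresholds(cohort, n_runs = 4, seed = 4)
  expect_equal(nrow(runs), 2 * 4 * 6)
  # each run block presents every condition exactly once
  counts <- runs |>
    dplyr::count(.data$listener, .data$run) |>
    dplyr::pull(.data$n)
  expect_true(all(counts == 6))
  final <- final_thresholds(runs)
  expect_equal(nrow(final), 12)
  # recovery within a few track standard errors of the configured values
  joined <- dplyr::inner_join(final, cohort,
                              by = c("listener", "condition"))
  expect_lt(max(abs(joined$threshold - joined$t707)), 3)
  s <- masking_release_summary(final)
  grand <- s$thresholds[s$thresholds$listener == "grand_average", ]
  expect_equal(nrow(grand), 6)
  # summary arithmetic is an exact linear function of the thresholds
  wide <- stats::setNames(grand$threshold, grand$condition)
  expect_equal(
    s$cmr$cmr_diotic[s$cmr$listener == "grand_average"],
    wide[["UN_0"]] - wide[["CM_0"]]
  )
  expect_equal(
    s$bmld$bmld_un[s$bmld$listener == "grand_average"],
    wide[["UN_0"]] - wide[["UN_150"]]
  )
})
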