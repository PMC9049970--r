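test_that("staircase follows the one-up/two-down rule and converges", {
  # observer always correct: tilt descends monotonically to the floor
  perfect <- observer_model(psychometric_slope = 1e-6, guess_error_prob = 0)
  sc <- run_staircase(staircase_spec(step_deg = 1, initial_tilt_deg = 10,
                                     min_tilt_deg = 0.5), perfect, 60, seed = 1)
  expect_true(all(diff(sc$tilt_deg) <= 0))
  expect_equal(min(sc$tilt_deg), 0.5)

  # chance observer stays at chance whatever the tilt path
  chance <- observer_model(psychometric_slope = 1e9, guess_error_prob = 0)
  sc2 <- run_staircase(staircase_spec(), chance, 4000, seed = 2)
  expect_lt(abs(mean(sc2$correct) - 0.5), 0.05)

  # determinism and parameter validation
  expect_identical(run_staircase(staircase_spec(), observer_model(), 50, seed = 7),
                   run_staircase(staircase_spec(), observer_model(), 50, seed = 7))
  expect_error(run_staircase(staircase_spec(), observer_model(), 0))
  expect_error(staircase_spec(step_deg = -1))
})

test_that("staircase asymptotes near the 1-up-2-down fixed point (~70%)", {
  sc <- run_staircase(staircase_spec(), observer_model(), 20000, seed = 1)
  acc <- 100 * mean(sc$correct[-seq_len(1000)])
  expect_lt(abs(acc - 70), 3)
  # independent of starting tilt
  sc2 <- run_staircase(staircase_spec(initial_tilt_deg = 18), observer_model(),
                       20000, seed = 3)
  expect_lt(abs(100 * mean(sc2$correct[-seq_len(1000)]) - 70), 3)
})

test_that("simulate_behavior: structure, determinism, calibration", {
  a <- simulate_behavior(seed = 42)
  b <- simulate_behavior(seed = 42)
  expect_identical(a$behavior, b$behavior)
  expect_silent(validate_behavior(a$behavior, default_protocol()))
  expect_equal(nrow(a$behavior), 64)

  # no lapses when lapse probabilities are zero
  nl <- simulate_behavior(observer = no_lapse_observer(), seed = 1)
  expect_false(any(nl$behavior$response == "none"))

  # easy runs at the fixed 20-deg tilt, ~90% correct over 40 runs
  proto40 <- protocol_params(n_runs = 40)
  big <- simulate_behavior(proto40, observer_model(), staircase_spec(),
                           ground_truth_spec(), seed = 5)
  easy <- big$behavior[big$behavior$difficulty == "easy", ]
  expect_true(all(abs(easy$tilt_deg) == 20))
  expect_lt(abs(100 * mean(easy$correct, na.rm = TRUE) - 90), 3)
  # hard-run accuracy near the staircase fixed point
  hard <- big$behavior[big$behavior$difficulty == "hard", ]
  expect_lt(abs(100 * mean(hard$correct, na.rm = TRUE) - 72), 6)
  # median RT near 0.55 s, within the ISI
  expect_lt(abs(stats::median(big$behavior$rt_s, na.rm = TRUE) - 0.55), 0.15)
  expect_true(all(big$behavior$rt_s <= 14.8, na.rm = TRUE))
})

test_that("simulate_bold: exact three-input response in the deterministic limit", {
  proto <- default_protocol()
  sim <- simulate_behavior(proto, no_lapse_observer(), staircase_spec(),
                           quiet_truth(trr_amplitude = 1), seed = 5)
  bold <- simulate_bold(sim$behavior, sim$truth, proto, n_voxels = 2,
                        seed = 5, n_background = 0)
  # both voxels identical and equal to the deterministic TRR
  expect_equal(bold$voxels[1, ], bold$voxels[2, ], tolerance = 1e-12)
  expect_equal(bold$voxels[1, ], bold$trr, tolerance = 1e-12)

  # noiseless BOLD lies exactly in the span of task + condition interactions
  task <- build_task_regressors(sim$behavior, canonical_hrf(), protocol = proto)
  nvol <- ncol(bold$voxels)
  cond <- build_condition_regressors(sim$behavior, nvol, proto$tr_s, proto)
  X <- suppressWarnings(assemble_design(task, cond, NULL, NULL, proto$tr_s))
  keep <- c("intercept", "fMRI_TO", "fMRI_BP", "fMRI_ToT",
            grep(":", colnames(X), value = TRUE))
  resid <- stats::lm.fit(unclass(X)[, keep], bold$voxels[1, ])$residuals
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("jitter lowers the trial-averaged response amplitude", {
  proto <- default_protocol()
  amp_for <- function(jit) {
    tr <- quiet_truth(trr_amplitude = 1)
    tr$jitter_sd_s[] <- jit
    sim <- simulate_behavior(proto, no_lapse_observer(), staircase_spec(), tr,
                             seed = 11)
    bold <- simulate_bold(sim$behavior, sim$truth, proto, n_voxels = 1,
                          seed = 11, n_background = 0)
    sig <- sampled_signal(bold$voxels[1, ], 1 / proto$tr_s)
    ep <- clean_and_epoch(sig, sim$behavior, proto)
    response_range(colMeans(ep$responses$data))
  }
  expect_gt(amp_for(0), amp_for(2))
})

test_that("synthetic V1 series is dominated by the task frequency", {
  # the session-level frequency response: 240-s run-averaged time course
  proto <- protocol_params()
  hits <- sapply(1:10, function(s) {
    sim <- simulate_behavior(proto, observer_model(), staircase_spec(),
                             ground_truth_spec(), seed = 700 + s)
    bold <- simulate_bold(sim$behavior, sim$truth, proto, n_voxels = 20,
                          seed = 700 + s)
    prep <- preprocess_roi(bold, sim$behavior, proto)
    avg <- rowMeans(matrix(prep$roi$values, nrow = 160))
    abs(spectrum_peak(sampled_signal(avg, 1 / 1.5))$frequency - 1 / 15) < 1e-9
  })
  expect_gte(mean(hits), 0.8)
})

test_that("simulate_physio: determinism, beat regularity, arousal coupling", {
  sim <- small_session(seed = 2)
  p1 <- simulate_physio(sim$behavior, sim$truth, seed = 9)
  p2 <- simulate_physio(sim$behavior, sim$truth, seed = 9)
  expect_identical(p1$pulse$values, p2$pulse$values)
  expect_identical(p1$respiration$values, p2$respiration$values)

  # zero arousal coupling: near-constant inter-beat interval
  p0 <- simulate_physio(sim$behavior, sim$truth, seed = 3, hr_coupling = 0)
  ibi <- diff(p0$beat_times)
  expect_lt(stats::sd(ibi) / mean(ibi), 0.01)

  # error-trial arousal raises recovered heart rate
  peaks <- refine_peaks(p1$pulse)
  pm <- pulse_metrics(peaks, trial_bins(sim$behavior))
  err <- which(sim$behavior$correct == 0)
  cor_ <- which(sim$behavior$correct == 1)
  expect_gt(mean(pm$hr_bpm[err], na.rm = TRUE), mean(pm$hr_bpm[cor_], na.rm = TRUE))
})

test_that("simulate_motion: six smooth zero-mean columns", {
  m <- simulate_motion(160, seed = 4)
  expect_equal(ncol(m), 6)
  expect_equal(colMeans(m), rep(0, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(simulate_motion(160, seed = 4), m)
  expect_true(all(simulate_motion(50, seed = 1, amplitude = 0) == 0))
})

test_that("simulate_pupil: blinks, determinism, condition-gain recovery", {
  pp <- protocol_params(trial_duration_s = 4, stim_duration_s = 0.2,
                        trials_per_run = 16, n_runs = 8)
  sim <- simulate_behavior(pp, observer_model(), staircase_spec(),
                           ground_truth_spec(), seed = 21)
  pup <- simulate_pupil(sim$behavior, sim$truth, pp, seed = 21)
  expect_identical(simulate_pupil(sim$behavior, sim$truth, pp, seed = 21)$pupil_area$values,
                   pup$pupil_area$values)
  noblink <- simulate_pupil(sim$behavior, sim$truth, pp, seed = 21,
                            blink_rate_hz = 0)
  expect_equal(nrow(noblink$blink_intervals), 0)
  expect_false(anyNA(noblink$pupil_area$values))

  # full pipeline recovers the incorrect > correct amplitude ordering
  clean <- deblink(pup$pupil_area, pup$blink_intervals)
  filt <- bandpass(clean)
  ev <- evoked_response(filt, sim$behavior, pp)
  expect_gt(ev$hard_incorrect$amplitude, ev$hard_correct$amplitude)
  expect_gt(ev$easy_incorrect$amplitude, ev$easy_correct$amplitude)
})

test_that("behavior, physio and pupil streams agree on trial counts", {
  sim <- small_session(seed = 6)
  bins <- trial_bins(sim$behavior)
  expect_equal(nrow(bins), nrow(sim$behavior))
  phys <- simulate_physio(sim$behavior, sim$truth, seed = 6)
  expect_equal(length(phys$pulse$values) / phys$pulse$rate_hz,
               4 * 240)   # 4 runs x 240 s
  expect_equal(nrow(sim$truth$trials), nrow(sim$behavior))
})
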