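test_that("task regressors: zero-RT degeneracy and RT scaling of ToT", {
  proto <- default_protocol()
  beh <- data.frame(observer_id = "O1", run_id = 1L, trial_index = 0L,
                    onset_s = 0, difficulty = "hard", tilt_deg = 1,
                    response = "cw", correct = 1L, rt_s = 0.5)
  hrf <- canonical_hrf()
  # RT -> 0: ToT identically 0, TO and BP coincide
  beh0 <- beh; beh0$rt_s <- 1e-9
  t0 <- build_task_regressors(beh0, hrf, protocol = proto)
  expect_true(all(t0$fMRI_ToT == 0))
  expect_equal(t0$fMRI_TO, t0$fMRI_BP, tolerance = 1e-12)

  # doubling RT doubles the ToT time-integral
  t1 <- build_task_regressors(beh, hrf, protocol = proto)
  beh2 <- beh; beh2$rt_s <- 1.0
  t2 <- build_task_regressors(beh2, hrf, protocol = proto)
  expect_equal(sum(t2$fMRI_ToT), 2 * sum(t1$fMRI_ToT), tolerance = 1e-6)

  # TO+BP amplitude decreases as RT grows from 0.2 to 4 s
  amp <- sapply(c(0.2, 1, 2, 4), function(rt) {
    b <- beh; b$rt_s <- rt
    tk <- build_task_regressors(b, hrf, protocol = proto)
    response_range(tk$fMRI_TO + tk$fMRI_BP)
  })
  expect_true(all(diff(amp) < 0))

  # button press outside the ISI is a data error
  behx <- beh; behx$rt_s <- 20
  expect_error(build_task_regressors(behx, hrf, protocol = proto), "outside")
  # lapse trials contribute no BP impulse / ToT boxcar
  behl <- beh; behl$rt_s <- NA; behl$correct <- NA; behl$response <- "none"
  tl <- build_task_regressors(behl, hrf, protocol = proto)
  expect_true(all(tl$fMRI_BP == 0) && all(tl$fMRI_ToT == 0))
  expect_gt(max(tl$fMRI_TO), 0)
})

test_that("design construction is linear over disjoint trial subsets", {
  proto <- default_protocol()
  sim <- simulate_behavior(proto, no_lapse_observer(), seed = 3)
  beh <- sim$behavior
  hrf <- canonical_hrf()
  full <- build_task_regressors(beh, hrf, protocol = proto)
  odd <- beh; odd$rt_s[seq(1, nrow(beh), 2)] <- NA
  odd$correct[seq(1, nrow(beh), 2)] <- NA; odd$response[seq(1, nrow(beh), 2)] <- "none"
  # drop TO too by removing rows: build from two disjoint subsets
  s1 <- beh[seq(1, nrow(beh), 2), ]; s2 <- beh[seq(2, nrow(beh), 2), ]
  r1 <- build_task_regressors(s1, hrf, protocol = proto)
  r2 <- build_task_regressors(s2, hrf, protocol = proto)
  expect_equal(r1$fMRI_TO + r2$fMRI_TO, full$fMRI_TO, tolerance = 1e-10)
  expect_equal(r1$fMRI_ToT + r2$fMRI_ToT, full$fMRI_ToT, tolerance = 1e-10)
})

test_that("physio predictors: kernel identities and band limiting", {
  n <- 50 * 120
  # constant input -> constant predictor (kernel sum x constant)
  const <- sampled_signal(rep(2, n), 50)
  flat <- sampled_signal(rep(0, n), 50)
  pred <- build_physio_predictors(const, const, tr_s = 1.5)
  kern_sum_card <- sum(evaluate_response_function(
    response_function_spec("cardiac"), seq(0, 32, by = 0.02)))
  mid <- 30:70          # past the causal ramp-in of the 32-s kernel
  expect_lt(stats::sd(pred$cardiac[mid]), 1e-6 * abs(mean(pred$cardiac[mid])))
  expect_equal(mean(pred$cardiac[mid]), 2 * kern_sum_card, tolerance = 1e-3)

  # unit impulse -> decimated kernel
  imp <- rep(0, n); imp[1] <- 1
  predi <- build_physio_predictors(sampled_signal(imp, 50),
                                   sampled_signal(imp, 50), tr_s = 1.5)
  kern <- evaluate_response_function(response_function_spec("respiration"),
                                     seq(0, 60, by = 0.02))
  deck <- decimate(sampled_signal(c(kern, rep(0, n - length(kern))), 50),
                   1 / 1.5)$values
  expect_equal(predi$respiration, deck, tolerance = 1e-8)

  # white-noise input: negligible spectral mass above the TR Nyquist
  set.seed(1)
  wn <- sampled_signal(stats::rnorm(n), 50)
  predw <- build_physio_predictors(wn, wn, tr_s = 1.5)
  # inspect the pre-decimation convolution spectrum via the TR series itself:
  # power above 0.8 x Nyquist of the TR rate should be tiny after decimation
  sp <- Mod(stats::fft(predw$respiration - mean(predw$respiration)))^2
  nn <- length(sp); fr <- (seq_len(nn) - 1) / nn * (1 / 1.5)
  hi <- fr > 0.8 * (1 / 3) & fr < (1 / 1.5) / 2
  expect_lt(sum(sp[hi]) / sum(sp[-1]), 0.01)
})

test_that("condition regressors code difficulty by run and accuracy by trial", {
  proto <- default_protocol()
  sim <- simulate_behavior(proto, no_lapse_observer(), seed = 9)
  beh <- sim$behavior
  nvol <- 4 * 160
  cond <- build_condition_regressors(beh, nvol, proto$tr_s, proto)
  expect_length(cond$difficulty, nvol)
  # per-run constant difficulty
  runs <- matrix(cond$difficulty, nrow = 160)
  expect_true(all(apply(runs, 2, function(v) length(unique(v)) == 1)))
  sched <- sapply(sort(unique(beh$run_id)),
                  function(r) beh$difficulty[beh$run_id == r][1] == "hard")
  expect_equal(runs[1, ], as.numeric(sched))
  # accuracy covers exactly 10 volumes per incorrect trial
  expect_equal(sum(cond$accuracy), 10 * sum(beh$correct == 0, na.rm = TRUE))
  # all-easy session: difficulty column all zero
  easy_beh <- beh; easy_beh$difficulty <- "easy"
  cond2 <- build_condition_regressors(easy_beh, nvol, proto$tr_s, proto)
  expect_true(all(cond2$difficulty == 0))
})

test_that("assembled design has the contracted 24 (or 18) labeled columns", {
  proto <- default_protocol()
  sim <- simulate_behavior(proto, observer_model(), seed = 3)
  task <- build_task_regressors(sim$behavior, canonical_hrf(), protocol = proto)
  nvol <- 4 * 160
  cond <- build_condition_regressors(sim$behavior, nvol, proto$tr_s, proto)
  set.seed(2)
  phys <- list(cardiac = stats::rnorm(nvol), respiration = stats::rnorm(nvol))
  mot <- simulate_motion(nvol, seed = 2)
  X <- assemble_design(task, cond, phys, mot, proto$tr_s)
  expect_equal(ncol(X), 24)
  expect_false(anyDuplicated(colnames(X)) > 0)
  expect_true(all(X[, "intercept"] == 1))
  X18 <- assemble_design(task, cond, phys, NULL, proto$tr_s)
  expect_equal(ncol(X18), 18)
  # interactions are elementwise products of their parents
  expect_equal(X[, "fMRI_TO:difficulty"], X[, "fMRI_TO"] * cond$difficulty,
               ignore_attr = TRUE)
  expect_equal(X[, "fMRI_ToT:difficulty:accuracy"],
               X[, "fMRI_ToT"] * cond$difficulty * cond$accuracy,
               ignore_attr = TRUE)
  # rank deficiency is flagged, not fatal
  condz <- cond; condz$difficulty <- rep(0, nvol)
  expect_warning(assemble_design(task, condz, phys, mot, proto$tr_s),
                 "rank deficient")
})

test_that("decimate preserves the passband and kills the stopband", {
  t50 <- (0:11999) / 50
  lo <- decimate(sampled_signal(sin(2 * pi * 0.05 * t50), 50), 1 / 1.5)
  expect_equal(sinusoid_fit(lo, 0.05)$amplitude, 1, tolerance = 0.01)
  hi <- decimate(sampled_signal(sin(2 * pi * 5 * t50), 50), 1 / 1.5)
  expect_lt(max(abs(hi$values)), 0.05)
  const <- decimate(sampled_signal(rep(3, 600), 50), 1 / 1.5)
  expect_equal(const$values, rep(3, length(const$values)), tolerance = 1e-9)
  expect_equal(length(const$values), floor(600 * (1 / 1.5) / 50))
  expect_error(decimate(sampled_signal(1:10, 1), 5), "upsampling|below")
})
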