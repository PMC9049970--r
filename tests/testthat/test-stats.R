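test_that("fit_mixed_model: exact recovery and the OLS limit", {
  proto <- default_protocol()
  sim <- simulate_behavior(proto, observer_model(), seed = 3)
  task <- build_task_regressors(sim$behavior, canonical_hrf(), protocol = proto)
  nvol <- 4 * 160
  cond <- build_condition_regressors(sim$behavior, nvol, proto$tr_s, proto)
  set.seed(2)
  phys <- list(cardiac = stats::rnorm(nvol), respiration = stats::rnorm(nvol))
  X <- assemble_design(task, cond, phys, simulate_motion(nvol, 2), proto$tr_s)

  # exact linear combination, no noise -> coefficients recovered
  beta_true <- stats::runif(24, -1, 1)
  y <- unclass(X) %*% beta_true
  f <- fit_mixed_model(X, as.numeric(y), random = NULL)
  expect_lt(max(abs(f$coefficients - beta_true)), 1e-6)
  expect_equal(f$fitted + f$residuals, as.numeric(y), tolerance = 1e-9)

  # OLS oracle equality in the zero-RE-variance limit
  set.seed(9)
  y2 <- as.numeric(y) + stats::rnorm(nvol)
  f2 <- fit_mixed_model(X, y2, random = NULL)
  expect_lt(max(abs(f2$coefficients - qr.solve(unclass(X), y2))), 1e-6)
})

test_that("random slopes recover per-observer amplitude scalings", {
  proto12 <- protocol_params(n_runs = 12)
  ses <- simulate_session(n_observers = 9, protocol = proto12, seed = 3101,
                          n_voxels = 20)
  g <- suppressWarnings(session_glmm(ses, proto12))
  re <- random_effects(g$fit)
  slopes <- re$fMRI_TO + re$fMRI_BP + re$fMRI_ToT   # combined-predictor deviation
  expect_gt(stats::cor(slopes, sapply(ses, function(s) s$scale)), 0.9)
})

test_that("contrast_ftest: row-space invariance and null uniformity", {
  set.seed(10)
  n <- 100
  X <- cbind(intercept = 1, a = stats::rnorm(n), b = stats::rnorm(n))
  class(X) <- c("design_matrix", class(X))
  y <- 2 + 0.5 * X[, "a"] + stats::rnorm(n)   # b truly zero
  f <- fit_mixed_model(X, y, random = NULL)
  L <- contrast_row(c("intercept", "a", "b"), c(b = 1))
  t1 <- contrast_ftest(f, L)
  t2 <- contrast_ftest(f, rbind(L, L))        # duplicated row, same F
  expect_equal(t1$F, t2$F, tolerance = 1e-10)
  expect_equal(t1$df1, t2$df1)
  expect_error(contrast_ftest(f, rbind(rep(0, 3))), "zero")

  # p uniform under the null (1,000 simulated fits)
  set.seed(11)
  ps <- replicate(1000, {
    yy <- 2 + 0.5 * X[, "a"] + stats::rnorm(n)
    contrast_ftest(fit_mixed_model(X, yy, random = NULL), L)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("exact_p arithmetic, bounds, and the minimum-p floor", {
  expect_equal(exact_p(0, 100000), 9.9999e-06)
  # truncation to 3 significant digits gives the reportable floor
  expect_equal(trunc(exact_p(0, 100000) * 1e8) / 1e8 * 1e6, 9.99, tolerance = 1e-9)
  expect_equal(exact_p(7, 100000), 8 / 100001, tolerance = 1e-15)
  expect_equal(trunc(exact_p(7, 100000) * 1e7) / 1e7, 7.99e-05)
  expect_equal(exact_p(100000, 100000), 1)
  expect_equal(exact_p(4999, 9999), 0.5)
  expect_gt(exact_p(0, 10), 0)
  expect_error(exact_p(5, 4))
  expect_error(exact_p(-1, 4))
})

test_that("permutation_test: tie convention, enumeration oracle, type I error", {
  # all values equal: every permutation ties -> p = 1
  pr <- permutation_test(rep(3, 10), rep(c("x", "y"), 5), m = 99, seed = 1)
  expect_equal(pr$b, pr$m)
  expect_equal(pr$p_exact, 1)

  # exhaustive mode matches an independent full-enumeration oracle (n <= 8)
  set.seed(3)
  v <- stats::rnorm(12)
  lab <- rep(c("g1", "g2"), each = 6)
  pr2 <- permutation_test(v, lab, exhaustive = TRUE)
  sel0 <- lab == "g1"
  obs <- mean(v[sel0]) - mean(v[!sel0])
  combos <- utils::combn(12, 6)
  null_or <- apply(combos, 2, function(ix) mean(v[ix]) - mean(v[-ix]))
  b_or <- sum(null_or >= obs - 1e-12)
  expect_equal(pr2$m, ncol(combos))
  expect_equal(pr2$p_exact, (b_or + 1) / (ncol(combos) + 1))
  # random sampling approximates the enumeration p
  pr3 <- permutation_test(v, lab, m = 9999, seed = 5)
  expect_lt(abs(pr3$p_exact - pr2$p_exact), 0.02)

  # type I error at alpha = 0.05 within the binomial interval under the null
  set.seed(7)
  nsim <- 400
  rej <- replicate(nsim, {
    vv <- stats::rnorm(16)
    permutation_test(vv, rep(c("a", "b"), each = 8), m = 199,
                     seed = sample.int(1e6, 1))$p_exact <= 0.05
  })
  ci <- stats::qbinom(c(0.025, 0.975), nsim, 0.05) / nsim
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("two_stage_fdr matches a step-by-step oracle and edge cases", {
  expect_equal(sum(two_stage_fdr(rep(1, 10), 0.05)$rejected), 0)
  expect_equal(sum(two_stage_fdr(rep(0.05 / 10, 10) / 2, 0.05)$rejected), 10)
  expect_error(two_stage_fdr(numeric(0)))
  expect_error(two_stage_fdr(c(0.5, 0)))

  # mixed null/alternative vector of 128 p-values vs an independent oracle
  set.seed(13)
  p_alt <- stats::pbeta(stats::runif(40), 1, 20)   # small p-values
  p_nul <- stats::runif(88)
  pv <- sample(c(p_alt, p_nul))
  got <- two_stage_fdr(pv, 0.05)
  # oracle: explicit two-stage linear step-up
  oracle_step <- function(p, q) {
    m <- length(p); srt <- sort(p)
    k <- max(c(0, which(srt <= q * seq_len(m) / m)))
    p <= if (k == 0) -Inf else srt[k]
  }
  q1 <- 0.05 / 1.05
  r1 <- sum(oracle_step(pv, q1))
  exp_rej <- if (r1 == 0) rep(FALSE, 128)
             else if (r1 == 128) rep(TRUE, 128)
             else oracle_step(pv, q1 * 128 / (128 - r1))
  expect_equal(got$rejected, exp_rej)
})

test_that("border_test: ties, forced extremes, shift invariance", {
  # constant map: all nulls tie the observed -> p = 1
  mp <- visual_field_map(pixel_deg = 1)
  mp$amp[] <- 2
  bt <- border_test(mp, border_spec(7.2, 100), seed = 1)
  expect_equal(bt$p_exact, 1)

  # amplitude concentrated in the screen-edge band -> minimal p
  mp2 <- visual_field_map(pixel_deg = 1)
  d_edge <- pmin(outer(rep(1, length(mp2$y)), 35 - abs(mp2$x)),
                 outer(19.75 - abs(mp2$y), rep(1, length(mp2$x))))
  mp2$amp <- (d_edge <= 7.2) * 1
  bt2 <- border_test(mp2, border_spec(7.2, 400), seed = 2)
  expect_equal(bt2$p_exact, 1 / 401)

  # p invariant to adding a constant to the whole map
  set.seed(3)
  mp3 <- visual_field_map(pixel_deg = 2)
  mp3$amp <- matrix(stats::rnorm(length(mp3$amp)), nrow(mp3$amp))
  b_a <- border_test(mp3, border_spec(7.2, 200), seed = 4)
  mp3$amp <- mp3$amp + 5
  b_b <- border_test(mp3, border_spec(7.2, 200), seed = 4)
  expect_equal(b_a$p_exact, b_b$p_exact)
  expect_error(border_test(mp3, border_spec(30, 10)), "thickness")
})

test_that("border_test p-values are roughly uniform under a Gaussian null", {
  # scaled down for runtime (coarse pixels, fewer repeats)
  set.seed(21)
  ps <- replicate(120, {
    mp <- visual_field_map(pixel_deg = 2)
    mp$amp <- matrix(stats::rnorm(length(mp$amp)), nrow(mp$amp))
    border_test(mp, border_spec(7.2, 99), seed = sample.int(1e6, 1))$p_exact
  })
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps < 0.2), 0.05)   # tails are populated
  expect_gt(mean(ps > 0.8), 0.05)
})

test_that("rt_modulation_sim reproduces the opposing RT effects", {
  proto <- default_protocol()
  sim <- simulate_behavior(protocol_params(n_runs = 8), observer_model(),
                           staircase_spec(), ground_truth_spec(), seed = 17)
  out <- rt_modulation_sim(sim$behavior)
  expect_true(all(c("tot_only", "to_bp", "all_three") %in% names(out)))
  for (cc in unique(paste(out$difficulty, out$accuracy))) {
    sub <- out[paste(out$difficulty, out$accuracy) == cc, ]
    if (nrow(sub) == 2) {
      fast <- sub[sub$rt_group == "fast", ]; slow <- sub[sub$rt_group == "slow", ]
      expect_gt(slow$tot_only, fast$tot_only)   # longer boxcar, higher amplitude
      expect_lt(slow$to_bp, fast$to_bp)         # wider impulse gap, lower amplitude
    }
  }
  # RT -> 0 limit: ToT amplitude vanishes, TO+BP doubles the single impulse
  behz <- sim$behavior[!is.na(sim$behavior$rt_s), ][1:8, ]
  behz$rt_s <- 1e-6
  outz <- rt_modulation_sim(behz)
  expect_lt(max(outz$tot_only), 1e-4)
  single <- response_range(evaluate_hrf(canonical_hrf(), seq(0, 15, by = 0.1)))
  expect_equal(outz$to_bp, rep(2 * single, nrow(outz)), tolerance = 1e-2)
})
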