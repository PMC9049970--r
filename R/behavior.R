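#' Ground-truth generative parameters for a simulated session
#'
#' Collects everything the BOLD/physio/pupil generators need: per-trial
#' amplitude gains for the three task inputs (trial onset TO, button press
#' BP, time-on-task ToT), per-trial temporal jitter, noise and coupling
#' levels, and the true HRF.
#'
#' Default condition gain rule (multiplicative):
#' gain = difficulty_gain^[hard] * error_gain^[incorrect]
#'        * easy_error_boost^[easy & incorrect], and `lapse_gain` on lapse
#' trials, so that hard > easy, incorrect > correct, and easy-incorrect and
#' lapse trials carry the largest responses.  Temporal jitter is zero-mean
#' Gaussian with a condition-dependent spread, largest for easy-correct and
#' smallest for easy-incorrect trials.
#'
#' @param difficulty_gain amplitude multiplier for hard trials (> 0).
#' @param error_gain amplitude multiplier for incorrect trials (> 0).
#' @param easy_error_boost extra multiplier for easy incorrect trials.
#' @param lapse_gain amplitude multiplier for lapse trials.
#' @param jitter_sd_s named numeric, per-condition jitter spreads (seconds)
#'   for easy_correct, hard_correct, hard_incorrect, easy_incorrect, lapse.
#' @param trr_amplitude overall TRR scale, percent signal change.
#' @param gain_noise_sd lognormal sd of trial-to-trial gain noise (0 = none).
#' @param noise_sd white noise sd per voxel (percent signal change).
#' @param drift_sd slow AR(1) drift sd per voxel (percent signal change).
#' @param drift_ar AR(1) coefficient of the drift.
#' @param global_sd,global_ar sd and AR(1) coefficient of the shared global
#'   component; faster than the voxel drift, emulating respiratory-scale
#'   whole-brain fluctuations.
#' @param global_coupling weight of the shared global component per voxel.
#' @param physio_coupling weight of the physiological artifact per voxel.
#' @param hrf_params_true the generating HRF, an [hrf_params()].
#' @return A `ground_truth_spec` list.
#' @export
ground_truth_spec <- function(difficulty_gain = 1.3, error_gain = 1.4,
                              easy_error_boost = 1.5, lapse_gain = 2.2,
                              jitter_sd_s = c(easy_correct = 1.0,
                                              hard_correct = 0.8,
                                              hard_incorrect = 0.6,
                                              easy_incorrect = 0.2,
                                              lapse = 0.8),
                              trr_amplitude = 0.3, gain_noise_sd = 0.2,
                              noise_sd = 1.0, drift_sd = 0.3, drift_ar = 0.98,
                              global_sd = 0.5, global_ar = 0.8,
                              global_coupling = 1.0, physio_coupling = 0.5,
                              hrf_params_true = canonical_hrf()) {
  gains <- c(difficulty_gain, error_gain, easy_error_boost, lapse_gain)
  if (any(gains <= 0)) stop("gains must be positive")
  if (any(jitter_sd_s < 0)) stop("jitter spreads must be >= 0")
  structure(list(difficulty_gain = difficulty_gain, error_gain = error_gain,
                 easy_error_boost = easy_error_boost, lapse_gain = lapse_gain,
                 jitter_sd_s = jitter_sd_s, trr_amplitude = trr_amplitude,
                 gain_noise_sd = gain_noise_sd, noise_sd = noise_sd,
                 drift_sd = drift_sd, drift_ar = drift_ar,
                 global_sd = global_sd, global_ar = global_ar,
                 global_coupling = global_coupling,
                 physio_coupling = physio_coupling,
                 hrf_params_true = hrf_params_true),
            class = "ground_truth_spec")
}

#' Condition label of behavior rows
#'
#' Combines difficulty and accuracy into the condition labels used
#' throughout ("easy_correct", "hard_incorrect", ...); missing accuracy
#' marks a lapse trial.
#'
#' @param difficulty character vector of "easy"/"hard".
#' @param correct 0/1 with NA for lapse trials.
#' @return character vector of condition labels.
#' @export
trial_condition <- function(difficulty, correct) {
  ifelse(is.na(correct), "lapse",
         paste(difficulty, ifelse(correct == 1, "correct", "incorrect"),
               sep = "_"))
}

# condition gain under the multiplicative rule
condition_gain <- function(truth, difficulty, correct) {
  g <- rep(1, length(difficulty))
  lapse <- is.na(correct)
  hard <- difficulty == "hard"
  wrong <- !lapse & correct == 0
  g[hard] <- g[hard] * truth$difficulty_gain
  g[wrong] <- g[wrong] * truth$error_gain
  g[wrong & !hard] <- g[wrong & !hard] * truth$easy_error_boost
  g[lapse] <- truth$lapse_gain
  g
}

#' Simulate a behavioral session
#'
#' Generates a per-trial behavior table for one observer: easy runs use a
#' fixed +/-20-deg tilt, hard runs follow the one-up/two-down staircase
#' (carried over across hard runs), lapses are inserted with per-condition
#' probabilities, and RTs are drawn from a truncated log-normal with
#' additive log-scale condition shifts.  Per-trial ground-truth gains and
#' temporal jitters are assigned from the condition rules in `truth`.
#'
#' @param protocol a [protocol_params()].
#' @param observer an [observer_model()].
#' @param staircase a [staircase_spec()].
#' @param truth a [ground_truth_spec()].
#' @param seed integer RNG seed.
#' @return list with `behavior` (data.frame: observer_id, run_id,
#'   trial_index, onset_s, difficulty, tilt_deg, response, correct, rt_s)
#'   and `truth` (the ground-truth spec plus per-trial `gain_TO`, `gain_BP`, `gain_ToT`,
#'   `jitter_s`).
#' @export
simulate_behavior <- function(protocol = protocol_params(),
                              observer = observer_model(),
                              staircase = staircase_spec(),
                              truth = ground_truth_spec(),
                              seed = 1L, observer_id = "O1") {
  stopifnot(inherits(protocol, "protocol_params"))
  if (length(protocol$difficulty_schedule) < 1L) stop("empty difficulty schedule")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  ntr <- protocol$trials_per_run
  rows <- vector("list", protocol$n_runs)
  tilt <- staircase$initial_tilt_deg   # staircase state persists across hard runs
  streak <- 0L
  for (r in seq_len(protocol$n_runs)) {
    difficulty <- protocol$difficulty_schedule[r]
    tilts <- numeric(ntr); correct <- integer(ntr)
    for (i in seq_len(ntr)) {
      if (difficulty == "easy") {
        tilts[i] <- staircase$max_tilt_deg
        correct[i] <- as.integer(stats::runif(1) < p_correct(observer, tilts[i]))
      } else {
        tilts[i] <- tilt
        ok <- stats::runif(1) < p_correct(observer, tilt)
        correct[i] <- as.integer(ok)
        if (ok) {
          streak <- streak + 1L
          if (streak >= staircase$n_down) {
            tilt <- max(staircase$min_tilt_deg, tilt - staircase$step_deg)
            streak <- 0L
          }
        } else {
          tilt <- min(staircase$max_tilt_deg, tilt + staircase$step_deg)
          streak <- 0L
        }
      }
    }
    sign <- sample(c(-1, 1), ntr, replace = TRUE)
    lapse_p <- if (difficulty == "easy") observer$lapse_prob_easy else observer$lapse_prob_hard
    lapse <- stats::runif(ntr) < lapse_p
    # truncated log-normal RTs with condition shifts
    mu <- observer$rt_log_mean +
      (difficulty == "hard") * observer$rt_condition_shifts[["hard"]] +
      (correct == 0) * observer$rt_condition_shifts[["incorrect"]]
    rt <- exp(stats::rnorm(ntr, mu, observer$rt_log_sd))
    over <- which(rt > protocol$isi_s)
    while (length(over) > 0) {
      rt[over] <- exp(stats::rnorm(length(over), mu[over], observer$rt_log_sd))
      over <- over[rt[over] > protocol$isi_s]
    }
    rows[[r]] <- data.frame(
      observer_id = observer_id, run_id = r, trial_index = seq_len(ntr) - 1L,
      onset_s = (seq_len(ntr) - 1L) * protocol$trial_duration_s,
      difficulty = difficulty, tilt_deg = sign * tilts,
      response = ifelse(lapse, "none",
                        ifelse(xor(sign > 0, correct == 0), "cw", "ccw")),
      correct = ifelse(lapse, NA_integer_, correct),
      rt_s = ifelse(lapse, NA_real_, rt),
      stringsAsFactors = FALSE
    )
  }
  behavior <- do.call(rbind, rows)
  n <- nrow(behavior)
  cond <- trial_condition(behavior$difficulty, behavior$correct)
  gain <- condition_gain(truth, behavior$difficulty, behavior$correct)
  if (truth$gain_noise_sd > 0)
    gain <- gain * exp(stats::rnorm(n, 0, truth$gain_noise_sd))
  jit_sd <- truth$jitter_sd_s[cond]
  truth_out <- truth
  truth_out$trials <- data.frame(
    observer_id = behavior$observer_id, run_id = behavior$run_id,
    trial_index = behavior$trial_index, condition = cond,
    gain_TO = gain, gain_BP = gain, gain_ToT = gain,
    jitter_s = stats::rnorm(n, 0, jit_sd)
  )
  list(behavior = behavior, truth = truth_out)
}

#' Validate a behavior table
#' @param behavior data.frame as returned by [simulate_behavior()].
#' @param protocol a [protocol_params()] for timing checks (optional).
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_behavior <- function(behavior, protocol = NULL) {
  need <- c("observer_id", "run_id", "trial_index", "onset_s", "difficulty",
            "tilt_deg", "response", "correct", "rt_s")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("behavior table missing columns: ",
                         paste(miss, collapse = ", "))
  lapse <- behavior$response == "none"
  if (!all(lapse == is.na(behavior$rt_s)) || !all(lapse == is.na(behavior$correct)))
    stop("lapse coding inconsistent: response 'none' must match missing rt/correct")
  if (any(behavior$rt_s <= 0, na.rm = TRUE)) stop("rt_s must be positive")
  if (!is.null(protocol)) {
    exp_on <- behavior$trial_index * protocol$trial_duration_s
    if (any(abs(behavior$onset_s - exp_on) > 1e-9))
      stop("onsets inconsistent with trial index and trial duration")
    if (any(behavior$rt_s > protocol$isi_s, na.rm = TRUE))
      stop("rt_s exceeds the interstimulus interval")
  }
  invisible(TRUE)
}
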