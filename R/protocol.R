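#' Experimental protocol parameters
#'
#' Fixed timing structure of the orientation-discrimination protocol: 15-s
#' trials (0.2-s stimulus + 14.8-s interstimulus interval), 16 trials per
#' 240-s run, BOLD sampled at TR = 1.5 s, task frequency 1/15 Hz.  The
#' pupillometry variant of the protocol uses a shorter 3.8-s ISI.
#'
#' @param trial_duration_s trial length in seconds.
#' @param stim_duration_s stimulus presentation in seconds.
#' @param trials_per_run trials in one run.
#' @param tr_s fMRI repetition time (sampling interval) in seconds.
#' @param n_runs number of runs in a session.
#' @param difficulty_schedule character vector, one of "easy"/"hard" per run;
#'   default alternates easy/hard over `n_runs`.
#' @param pupil_isi_s interstimulus interval of the pupil protocol (seconds).
#' @return A `protocol_params` list with derived fields `isi_s`,
#'   `run_duration_s` and `task_freq_hz`.
#' @export
protocol_params <- function(trial_duration_s = 15, stim_duration_s = 0.2,
                            trials_per_run = 16L, tr_s = 1.5, n_runs = 4L,
                            difficulty_schedule = NULL, pupil_isi_s = 3.8) {
  if (trial_duration_s <= stim_duration_s) stop("trial shorter than stimulus")
  if (trials_per_run < 1L || n_runs < 1L) stop("counts must be >= 1")
  if (tr_s <= 0) stop("tr_s must be positive")
  if (is.null(difficulty_schedule))
    difficulty_schedule <- rep(c("easy", "hard"), length.out = n_runs)
  if (length(difficulty_schedule) != n_runs)
    stop("difficulty_schedule length must equal n_runs")
  if (!all(difficulty_schedule %in% c("easy", "hard")))
    stop("difficulty_schedule entries must be 'easy' or 'hard'")
  p <- list(
    trial_duration_s = trial_duration_s,
    stim_duration_s  = stim_duration_s,
    isi_s            = trial_duration_s - stim_duration_s,
    trials_per_run   = as.integer(trials_per_run),
    run_duration_s   = trials_per_run * trial_duration_s,
    tr_s             = tr_s,
    task_freq_hz     = 1 / trial_duration_s,
    n_runs           = as.integer(n_runs),
    difficulty_schedule = difficulty_schedule,
    pupil_isi_s      = pupil_isi_s
  )
  class(p) <- "protocol_params"
  p
}

#' One-up/two-down staircase specification
#'
#' Tilt magnitude decreases by `step_deg` after two consecutive correct
#' responses and increases by `step_deg` after every incorrect response,
#' which drives percent correct towards the 1-up-2-down fixed point
#' (sqrt(1/2) ~ 70.7%).  Easy runs bypass the staircase with a fixed
#' +/-20 deg tilt (`max_tilt_deg`).
#'
#' @param step_deg staircase step in degrees (> 0).
#' @param initial_tilt_deg starting tilt magnitude.
#' @param min_tilt_deg,max_tilt_deg clamp range for the tilt magnitude.
#' @return A `staircase_spec` list; `n_up = 1`, `n_down = 2` are fixed.
#' @export
staircase_spec <- function(step_deg = 0.5, initial_tilt_deg = 5,
                           min_tilt_deg = 0.1, max_tilt_deg = 20) {
  if (step_deg <= 0) stop("step_deg must be positive")
  if (!(0 < min_tilt_deg && min_tilt_deg <= initial_tilt_deg &&
        initial_tilt_deg <= max_tilt_deg))
    stop("need 0 < min_tilt_deg <= initial_tilt_deg <= max_tilt_deg")
  structure(list(n_up = 1L, n_down = 2L, step_deg = step_deg,
                 initial_tilt_deg = initial_tilt_deg,
                 min_tilt_deg = min_tilt_deg, max_tilt_deg = max_tilt_deg),
            class = "staircase_spec")
}

#' Simulated observer model
#'
#' Stochastic stand-in for a human observer.  Percent correct follows a
#' folded cumulative-Gaussian psychometric function of tilt magnitude with a
#' guess rate of 0.5 and an attentional error rate `guess_error_prob` that
#' caps asymptotic accuracy at `1 - guess_error_prob` (default 0.1, so easy
#' 20-deg trials land near 90% correct).  Response times are log-normal,
#' truncated to (0, ISI], with additive condition shifts on the log scale;
#' defaults give a median RT near 0.55 s with ~86% of RTs under 1 s.  Lapses
#' (no response) occur independently with per-condition probabilities.
#'
#' @param psychometric_slope scale (degrees) of the cumulative-Gaussian.
#' @param guess_error_prob probability of a stimulus-independent error.
#' @param lapse_prob_easy,lapse_prob_hard per-trial no-response probability.
#' @param rt_log_mean,rt_log_sd log-normal RT parameters (log-seconds).
#' @param rt_condition_shifts named numeric, additive log-scale RT shifts for
#'   conditions "hard" and "incorrect".
#' @return An `observer_model` list.
#' @export
observer_model <- function(psychometric_slope = 2,
                           guess_error_prob = 0.10,
                           lapse_prob_easy = 0.0668,
                           lapse_prob_hard = 0.0448,
                           rt_log_mean = log(0.552),
                           rt_log_sd = 0.545,
                           rt_condition_shifts = c(hard = 0.25, incorrect = 0.05)) {
  probs <- c(guess_error_prob, lapse_prob_easy, lapse_prob_hard)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (psychometric_slope <= 0) stop("psychometric_slope must be positive")
  if (rt_log_sd <= 0) stop("rt_log_sd must be positive")
  structure(list(psychometric_slope = psychometric_slope,
                 guess_error_prob = guess_error_prob,
                 lapse_prob_easy = lapse_prob_easy,
                 lapse_prob_hard = lapse_prob_hard,
                 rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd,
                 rt_condition_shifts = rt_condition_shifts),
            class = "observer_model")
}

#' Probability correct for an observer at a given tilt
#'
#' p(|tilt|) = 0.5 + (0.5 - lambda) * (2 Phi(|tilt|/sigma) - 1), a folded
#' cumulative Gaussian rising from chance (0.5) at zero tilt to
#' 1 - lambda at large tilt, where lambda is the attentional error rate.
#'
#' @param observer an `observer_model`.
#' @param tilt_deg signed or unsigned tilt in degrees.
#' @return probability of a correct response, in [0.5, 1 - lambda].
#' @export
p_correct <- function(observer, tilt_deg) {
  z <- abs(tilt_deg) / observer$psychometric_slope
  0.5 + (0.5 - observer$guess_error_prob) * (2 * stats::pnorm(z) - 1)
}
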