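#' Simulate voxelwise BOLD percent-signal-change series
#'
#' Each voxel is built as
#' shared TRR + global component + physiological artifact + noise, where the
#' TRR is the three-input (trial onset, button press, time-on-task)
#' convolution with the true HRF, with per-trial temporal jitter applied as
#' a common shift of the three events, and per-trial amplitude gains applied
#' as a trial-resolution multiplicative modulation of the sampled response.
#' Noise is white Gaussian plus a first-order autoregressive slow drift.
#' Units are percent signal change at rate 1/TR.
#'
#' @param behavior behavior table from [simulate_behavior()].
#' @param truth `ground_truth_spec` carrying per-trial gains/jitters (the
#'   `$trials` field added by [simulate_behavior()]).
#' @param protocol a [protocol_params()].
#' @param n_voxels number of ROI voxels carrying the TRR.
#' @param seed integer RNG seed.
#' @param physio optional list with `pulse` and `respiration`
#'   [sampled_signal()]s; when supplied, the physiological artifact is their
#'   predicted-BOLD convolution scaled by `truth$physio_coupling`.
#' @param n_background number of additional brain voxels without a TRR
#'   (global + artifact + noise only), emulating the fact that the ROI is a
#'   small fraction of the brain so the global signal is not dominated by
#'   the TRR; default 10 x n_voxels.
#' @return a `voxel_signals` list: `voxels` (ROI rows first, then
#'   background), `roi_mask` (indices of the ROI rows), `tr_s`, `global`
#'   (the injected global component) and `artifact`.
#' @export
simulate_bold <- function(behavior, truth, protocol = protocol_params(),
                          n_voxels = 20, seed = 1L, physio = NULL,
                          n_background = 10 * n_voxels) {
  if (is.null(truth$trials)) stop("truth must carry per-trial gains (run simulate_behavior)")
  if (nrow(truth$trials) != nrow(behavior))
    stop("behavior and truth trial counts do not match")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  tr_s <- protocol$tr_s
  n_runs <- length(unique(behavior$run_id))
  vol_per_run <- round(protocol$run_duration_s / tr_s)
  n_vol <- n_runs * vol_per_run
  vol_per_trial <- round(protocol$trial_duration_s / tr_s)

  task <- build_task_regressors(behavior, truth$hrf_params_true,
                                working_rate_hz = 10, protocol = protocol,
                                jitter_s = truth$trials$jitter_s)
  dec <- function(v) {
    runs <- split(v, rep(seq_len(length(v) / task$run_len), each = task$run_len))
    unlist(lapply(runs, function(x)
      decimate(sampled_signal(x, task$working_rate_hz), 1 / tr_s)$values),
      use.names = FALSE)
  }
  TO <- dec(task$fMRI_TO); BP <- dec(task$fMRI_BP); ToT <- dec(task$fMRI_ToT)

  # trial-resolution gain vectors at TR
  gvec <- function(g) {
    out <- numeric(n_vol)
    for (k in seq_len(nrow(behavior))) {
      ri <- match(behavior$run_id[k], sort(unique(behavior$run_id)))
      i0 <- (ri - 1) * vol_per_run + behavior$trial_index[k] * vol_per_trial + 1
      out[i0:min(i0 + vol_per_trial - 1, n_vol)] <- g[k]
    }
    out
  }
  trr <- truth$trr_amplitude *
    (gvec(truth$trials$gain_TO) * TO + gvec(truth$trials$gain_BP) * BP +
     gvec(truth$trials$gain_ToT) * ToT)

  ar1 <- function(n, sd, phi) {
    if (sd == 0) return(numeric(n))
    e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
    stats::filter(e, phi, method = "recursive")
  }
  glob <- as.numeric(ar1(n_vol, truth$global_sd, truth$global_ar))
  phi <- truth$drift_ar

  artifact <- numeric(n_vol)
  if (!is.null(physio) && truth$physio_coupling != 0) {
    pred <- build_physio_predictors(physio$pulse, physio$respiration,
                                    tr_s = tr_s, n_volumes = n_vol)
    sc <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v
    artifact <- truth$physio_coupling * (sc(pred$cardiac) + sc(pred$respiration)) / 2
  }

  n_total <- n_voxels + n_background
  shared <- truth$global_coupling * glob + artifact
  noise <- matrix(stats::rnorm(n_vol * n_total, 0, truth$noise_sd), n_vol, n_total)
  if (truth$drift_sd > 0) {
    innov <- matrix(stats::rnorm(n_vol * n_total, 0,
                                 truth$drift_sd * sqrt(1 - phi^2)),
                    n_vol, n_total)
    noise <- noise + stats::filter(innov, phi, method = "recursive")
  }
  vox <- t(noise + shared)
  vox[seq_len(n_voxels), ] <- vox[seq_len(n_voxels), , drop = FALSE] +
    rep(trr, each = n_voxels)
  structure(list(voxels = vox, roi_mask = seq_len(n_voxels), tr_s = tr_s,
                 n_runs = n_runs, global = glob, artifact = artifact,
                 trr = trr),
            class = "voxel_signals")
}

#' Simulate pulse-oximeter and respiration-belt traces
#'
#' Pulse: a raised-cosine beat template placed at quasi-periodic beat times
#' whose instantaneous rate is modulated by the per-trial arousal gain.
#' Respiration: a phase- and amplitude-modulated sinusoid; arousal raises
#' volume and lowers breathing frequency.  Both traces are sampled at
#' 50 Hz and deterministic given the seed.
#'
#' @param behavior behavior table.
#' @param truth `ground_truth_spec` with per-trial gains.
#' @param protocol a [protocol_params()].
#' @param seed integer RNG seed.
#' @param base_hr_bpm resting heart rate (beats/minute).
#' @param hr_coupling fractional HR increase per unit arousal gain above 1.
#' @param hrv_sd fractional inter-beat-interval noise (sd / mean).
#' @param base_resp_hz resting breathing frequency.
#' @param resp_amp_coupling,resp_freq_coupling arousal couplings of
#'   respiration amplitude (positive) and frequency (negative effect).
#' @param rate_hz output sampling rate.
#' @return list with `pulse` and `respiration` [sampled_signal()]s and
#'   `beat_times` (true beat times, seconds).
#' @export
simulate_physio <- function(behavior, truth, protocol = protocol_params(),
                            seed = 1L, base_hr_bpm = 70, hr_coupling = 0.15,
                            hrv_sd = 0.008, base_resp_hz = 0.25,
                            resp_amp_coupling = 0.3, resp_freq_coupling = 0.15,
                            rate_hz = 50) {
  if (nrow(behavior) == 0) stop("behavior is empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_runs <- length(unique(behavior$run_id))
  total_s <- n_runs * protocol$run_duration_s
  n <- round(total_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz

  gains <- if (!is.null(truth$trials))
    condition_gain(truth, behavior$difficulty, behavior$correct) else rep(1, nrow(behavior))
  gain_at <- function(t) {
    ri <- pmin(floor(t / protocol$run_duration_s), n_runs - 1)
    k <- ri * protocol$trials_per_run +
      pmin(floor((t - ri * protocol$run_duration_s) / protocol$trial_duration_s),
           protocol$trials_per_run - 1) + 1
    gains[pmin(pmax(k, 1), length(gains))]
  }

  # beat point process
  beats <- numeric(0)
  t <- stats::runif(1, 0, 0.5)
  while (t < total_s) {
    beats <- c(beats, t)
    hr <- base_hr_bpm * (1 + hr_coupling * (gain_at(t) - 1))
    ibi <- (60 / hr) * (1 + stats::rnorm(1, 0, hrv_sd))
    t <- t + max(ibi, 0.25)
  }
  w <- 0.25                                  # half-width of beat template (s)
  pulse <- numeric(n)
  hw <- ceiling(w * rate_hz)
  for (b in beats) {
    ib <- round(b * rate_hz) + 1
    idx <- max(1, ib - hw):min(n, ib + hw)
    amp <- 0.5 * (1 + cos(pi * (tt[idx] - b) / w))
    pulse[idx] <- pulse[idx] + amp * (abs(tt[idx] - b) < w)
  }
  pulse <- pulse + stats::rnorm(n, 0, 0.01)

  g_t <- gain_at(tt)
  freq <- base_resp_hz * (1 - resp_freq_coupling * (g_t - 1))
  phase <- 2 * pi * cumsum(freq) / rate_hz
  amp <- 1 + resp_amp_coupling * (g_t - 1)
  # positive baseline so downstream percent-change conversion is well posed
  resp <- 10 + amp * sin(phase) + stats::rnorm(n, 0, 0.02)

  list(pulse = sampled_signal(pulse, rate_hz, 0, "a.u."),
       respiration = sampled_signal(resp, rate_hz, 0, "a.u."),
       beat_times = beats)
}

#' Simulate six head-motion traces
#'
#' Smooth random walks (cumulative white noise smoothed by a moving
#' average), demeaned over the run, for roll, pitch, yaw, x, y and z.
#'
#' @param n_volumes number of volumes.
#' @param seed integer RNG seed.
#' @param amplitude step sd of the walk; 0 gives all-zero columns.
#' @return n_volumes x 6 matrix with named columns.
#' @export
simulate_motion <- function(n_volumes, seed = 1L, amplitude = 0.02) {
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 1L) stop("n_volumes must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  one <- function() {
    x <- cumsum(stats::rnorm(n_volumes, 0, amplitude))
    if (n_volumes >= 5) x <- stats::filter(x, rep(1 / 5, 5), sides = 2)
    x <- as.numeric(x); x[is.na(x)] <- 0
    x - mean(x)
  }
  m <- sapply(seq_len(6), function(i) one())
  colnames(m) <- c("roll", "pitch", "yaw", "x", "y", "z")
  m
}

# canonical pupil response kernel (Erlang-like), peak 1 at t_max
pupil_kernel <- function(times, n = 10.1, t_max = 0.93) {
  v <- (times / t_max)^n * exp(n * (1 - times / t_max))
  v[times < 0] <- 0
  v
}

#' Simulate pupil-area and gaze traces with blinks
#'
#' Per-trial pupil dilation is a condition-gain-scaled canonical pupil
#' response added to a slowly drifting baseline; blinks are inserted as
#' missing (NA) spans; gaze is fixation plus small Gaussian jitter.  Uses
#' the pupil protocol timing (3.8-s ISI, 4-s trials).
#'
#' @param behavior behavior table generated with the pupil protocol timing.
#' @param truth `ground_truth_spec`.
#' @param protocol a [protocol_params()] whose `trial_duration_s` reflects
#'   the pupil protocol (stimulus + `pupil_isi_s`).
#' @param seed integer RNG seed.
#' @param rate_hz sampling rate (500 Hz).
#' @param blink_rate_hz mean blink rate (events/second); 0 disables blinks.
#' @param base_amp pupil response amplitude in arbitrary units.
#' @param gaze_sd_deg sd of gaze jitter around fixation, degrees.
#' @return list with `pupil_area` ([sampled_signal()], NA inside blinks),
#'   `gaze_xy` (two-column matrix, degrees), `blink_intervals`
#'   (two-column matrix of start/end seconds) and `rate_hz`.
#' @export
simulate_pupil <- function(behavior, truth, protocol = NULL, seed = 1L,
                           rate_hz = 500, blink_rate_hz = 0.1,
                           base_amp = 1, gaze_sd_deg = 0.2) {
  if (is.null(protocol))
    protocol <- protocol_params(trial_duration_s = 4, stim_duration_s = 0.2,
                                trials_per_run = 16L, n_runs = 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_runs <- length(unique(behavior$run_id))
  total_s <- n_runs * protocol$run_duration_s
  n <- round(total_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz

  gains <- condition_gain(truth, behavior$difficulty, behavior$correct)
  run_ids <- sort(unique(behavior$run_id))
  onset_abs <- (match(behavior$run_id, run_ids) - 1) * protocol$run_duration_s +
    behavior$onset_s
  pupil <- 5 + 0.3 * sin(2 * pi * tt / 60) + stats::rnorm(n, 0, 0.02)
  for (k in seq_len(nrow(behavior))) {
    idx <- which(tt >= onset_abs[k] & tt < onset_abs[k] + 6)
    pupil[idx] <- pupil[idx] + base_amp * gains[k] *
      pupil_kernel(tt[idx] - onset_abs[k])
  }
  blink_intervals <- matrix(numeric(0), 0, 2)
  if (blink_rate_hz > 0) {
    n_blinks <- stats::rpois(1, blink_rate_hz * total_s)
    if (n_blinks > 0) {
      starts <- sort(stats::runif(n_blinks, 0, total_s - 0.5))
      durs <- stats::runif(n_blinks, 0.1, 0.4)
      blink_intervals <- cbind(start = starts, end = pmin(starts + durs, total_s))
      for (b in seq_len(n_blinks)) {
        idx <- which(tt >= blink_intervals[b, 1] & tt <= blink_intervals[b, 2])
        pupil[idx] <- NA_real_
      }
    }
  }
  gaze <- cbind(x = stats::rnorm(n, 0, gaze_sd_deg),
                y = stats::rnorm(n, 0, gaze_sd_deg))
  list(pupil_area = sampled_signal(pupil, rate_hz, 0, "a.u."),
       gaze_xy = gaze, blink_intervals = blink_intervals, rate_hz = rate_hz)
}

#' Simulate a complete multi-observer session set
#'
#' Convenience wrapper generating behavior, ground truth, physiology,
#' motion and ROI BOLD for several observers with observer-specific
#' amplitude scalings, ready for design assembly and mixed-model fitting.
#'
#' @param n_observers number of observers.
#' @param protocol a [protocol_params()].
#' @param truth a [ground_truth_spec()].
#' @param observer an [observer_model()].
#' @param staircase a [staircase_spec()].
#' @param seed integer RNG seed (observer o uses seed + o).
#' @param n_voxels voxels per observer.
#' @param observer_scale_sd lognormal sd of per-observer amplitude scaling.
#' @return list of per-observer lists with `behavior`, `truth`, `physio`,
#'   `motion`, `bold` and `scale`.
#' @export
simulate_session <- function(n_observers = 9, protocol = protocol_params(),
                             truth = ground_truth_spec(),
                             observer = observer_model(),
                             staircase = staircase_spec(), seed = 1L,
                             n_voxels = 20, observer_scale_sd = 0.3) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  scales <- exp(stats::rnorm(n_observers, 0, observer_scale_sd))
  lapply(seq_len(n_observers), function(o) {
    tr_o <- truth
    tr_o$trr_amplitude <- truth$trr_amplitude * scales[o]
    sim <- simulate_behavior(protocol, observer, staircase, tr_o,
                             seed = seed + o, observer_id = sprintf("O%d", o))
    phys <- simulate_physio(sim$behavior, sim$truth, protocol, seed = seed + o)
    n_vol <- length(unique(sim$behavior$run_id)) *
      round(protocol$run_duration_s / protocol$tr_s)
    mot <- simulate_motion(n_vol, seed = seed + o)
    bold <- simulate_bold(sim$behavior, sim$truth, protocol, n_voxels,
                          seed = seed + o, physio = phys)
    list(behavior = sim$behavior, truth = sim$truth, physio = phys,
         motion = mot, bold = bold, scale = scales[o])
  })
}
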