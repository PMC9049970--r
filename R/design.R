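#' Zero-phase frequency-domain filter
#'
#' Applies a real, nonnegative gain function of frequency to a signal via
#' the FFT, after reflection padding to suppress wrap-around.  Because the
#' gain is real the filter has exactly zero phase, the frequency-domain
#' equivalent of a forward-backward (filtfilt) pass.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate.
#' @param gain_fun function of frequency (Hz, >= 0) returning gains in [0,1].
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
fft_filter <- function(x, rate_hz, gain_fun) {
  n <- length(x)
  if (n < 2) return(x)
  xp <- c(x, rev(x))                       # reflection pad to length 2n
  np <- length(xp)
  f <- (seq_len(np) - 1) / np * rate_hz
  f <- pmin(f, rate_hz - f)                # two-sided -> folded frequency
  g <- gain_fun(f)
  Re(stats::fft(stats::fft(xp) * g, inverse = TRUE))[seq_len(n)] / np
}

butter_lp_gain <- function(fc, order) function(f) 1 / (1 + (f / fc)^(2 * order))

#' Decimate a sampled signal
#'
#' Zero-phase low-pass filtering at 0.8 x the target Nyquist frequency
#' (squared 8th-order Butterworth magnitude applied in the frequency
#' domain), followed by sample selection.  Output length is
#' `floor(n * target / source)`.
#'
#' @param signal a [sampled_signal()].
#' @param target_rate_hz new rate; must be below the source rate.
#' @return a [sampled_signal()] at the target rate.
#' @export
decimate <- function(signal, target_rate_hz) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (target_rate_hz >= signal$rate_hz)
    stop("target rate must be below the source rate (no upsampling)")
  fc <- 0.8 * target_rate_hz / 2
  y <- fft_filter(signal$values, signal$rate_hz, butter_lp_gain(fc, 8))
  n_out <- floor(length(signal$values) * target_rate_hz / signal$rate_hz)
  idx <- floor((seq_len(n_out) - 1) * signal$rate_hz / target_rate_hz) + 1
  sampled_signal(y[idx], target_rate_hz, signal$start_s, signal$units)
}

#' Build the three HRF-convolved task regressors
#'
#' Places unit-area impulses at trial onsets (TO) and button presses (BP)
#' and unit-height boxcars spanning onset to button press (time on task,
#' ToT) on a fine working grid, and convolves each event stream with the
#' observer's HRF.  Lapse trials contribute a TO impulse only.  Runs are
#' treated as independent acquisitions: the convolution does not spill
#' across run boundaries.
#'
#' @param behavior behavior table (see [simulate_behavior()]).
#' @param hrf an [hrf_params()] object.
#' @param working_rate_hz impulse-placement rate, >= 10 Hz.
#' @param protocol a [protocol_params()] giving the run duration.
#' @param jitter_s optional per-trial common shift (seconds) applied to all
#'   three events of each trial (used by the generator; default 0).
#' @return list of class `task_regressors` with numeric vectors `fMRI_TO`,
#'   `fMRI_BP`, `fMRI_ToT` at `working_rate_hz`, plus `working_rate_hz` and
#'   `run_len` (samples per run).
#' @export
build_task_regressors <- function(behavior, hrf, working_rate_hz = 10,
                                  protocol = protocol_params(),
                                  jitter_s = NULL) {
  if (working_rate_hz < 10) stop("working_rate_hz must be >= 10")
  if (any(behavior$rt_s > protocol$isi_s, na.rm = TRUE))
    stop("button press outside the interstimulus interval")
  dt <- 1 / working_rate_hz
  run_len <- round(protocol$run_duration_s * working_rate_hz)
  runs <- sort(unique(behavior$run_id))
  if (is.null(jitter_s)) jitter_s <- rep(0, nrow(behavior))
  kern <- evaluate_hrf(hrf, seq(0, hrf$support_s, by = dt))

  to <- bp <- tot <- numeric(0)
  for (r in runs) {
    sel <- behavior$run_id == r
    on_t <- behavior$onset_s[sel] + jitter_s[sel]
    rt <- behavior$rt_s[sel]
    x_to <- x_bp <- x_tot <- numeric(run_len)
    oi <- pmin(pmax(round(on_t * working_rate_hz) + 1, 1), run_len)
    for (k in seq_along(oi)) {
      x_to[oi[k]] <- x_to[oi[k]] + working_rate_hz      # unit area
      if (!is.na(rt[k])) {
        bi <- pmin(pmax(round((on_t[k] + rt[k]) * working_rate_hz) + 1, 1), run_len)
        x_bp[bi] <- x_bp[bi] + working_rate_hz
        if (bi > oi[k])                                  # unit-height boxcar
          x_tot[oi[k]:(bi - 1)] <- x_tot[oi[k]:(bi - 1)] + 1
      }
    }
    to <- c(to, conv_causal(x_to, kern) * dt)
    bp <- c(bp, conv_causal(x_bp, kern) * dt)
    tot <- c(tot, conv_causal(x_tot, kern) * dt)
  }
  structure(list(fMRI_TO = to, fMRI_BP = bp, fMRI_ToT = tot,
                 working_rate_hz = working_rate_hz, run_len = run_len),
            class = "task_regressors")
}

# causal discrete convolution truncated to length(x)
conv_causal <- function(x, k) {
  n <- length(x)
  y <- stats::convolve(x, rev(k), type = "open")
  y[seq_len(n)]
}

#' Canonical physiological response function specification
#'
#' Kernel shapes for predicting BOLD from raw physiological traces: the
#' cardiac response function
#' CRF(t) = a1 t^p e^(-t/tau) - a2 exp(-(t - mu)^2 / (2 s^2)) and the
#' respiration response function
#' RRF(t) = b1 t^q e^(-t/tau1) - b2 t^r e^(-t/tau2), with the published
#' canonical constants as overridable defaults.
#'
#' @param kind "cardiac" or "respiration".
#' @param coefficients named numeric overriding the canonical constants.
#' @param support_s kernel support in seconds.
#' @return a `response_function_spec` list.
#' @export
response_function_spec <- function(kind = c("cardiac", "respiration"),
                                   coefficients = NULL, support_s = NULL) {
  kind <- match.arg(kind)
  co <- if (kind == "cardiac")
    c(a1 = 0.6, p = 2.7, tau = 1.6, a2 = 16 / sqrt(2 * pi * 9), mu = 12, s = 3)
  else
    c(b1 = 0.6, q = 2.1, tau1 = 1.6, b2 = 0.0023, r = 3.54, tau2 = 4.25)
  if (!is.null(coefficients)) co[names(coefficients)] <- coefficients
  if (is.null(support_s)) support_s <- if (kind == "cardiac") 32 else 60
  structure(list(kind = kind, coefficients = co, support_s = support_s),
            class = "response_function_spec")
}

#' Evaluate a physiological response kernel
#' @param spec a [response_function_spec()].
#' @param times nonnegative times in seconds.
#' @return numeric kernel values.
#' @export
evaluate_response_function <- function(spec, times) {
  co <- spec$coefficients
  v <- if (spec$kind == "cardiac")
    co["a1"] * times^co["p"] * exp(-times / co["tau"]) -
      co["a2"] * exp(-(times - co["mu"])^2 / (2 * co["s"]^2))
  else
    co["b1"] * times^co["q"] * exp(-times / co["tau1"]) -
      co["b2"] * times^co["r"] * exp(-times / co["tau2"])
  v[times > spec$support_s] <- 0
  unname(v)
}

#' Predicted-BOLD physiological regressors
#'
#' Convolves each raw physiological trace with its canonical response
#' kernel at the trace's native sampling rate, and only then decimates to
#' the fMRI rate.
#'
#' @param pulse,respiration [sampled_signal()] traces at their raw rates.
#' @param specs list with elements `cardiac` and `respiration`
#'   ([response_function_spec()]); defaults to the canonical kernels.
#' @param tr_s fMRI sampling interval.
#' @param n_volumes optional output length to trim/pad to.
#' @return list with numeric `cardiac` and `respiration` columns at TR.
#' @export
build_physio_predictors <- function(pulse, respiration, specs = NULL,
                                    tr_s = 1.5, n_volumes = NULL) {
  if (is.null(specs))
    specs <- list(cardiac = response_function_spec("cardiac"),
                  respiration = response_function_spec("respiration"))
  if (specs$cardiac$kind != "cardiac" || specs$respiration$kind != "respiration")
    stop("specs must pair a cardiac and a respiration kernel")
  one <- function(sig, spec) {
    dt <- 1 / sig$rate_hz
    kern <- evaluate_response_function(spec, seq(0, spec$support_s, by = dt))
    conv <- conv_causal(sig$values, kern)
    decimate(sampled_signal(conv, sig$rate_hz, sig$start_s), 1 / tr_s)$values
  }
  card <- one(pulse, specs$cardiac)
  resp <- one(respiration, specs$respiration)
  if (!is.null(n_volumes)) {
    fix <- function(v) { length(v) <- n_volumes; v[is.na(v)] <- 0; v }
    card <- fix(card); resp <- fix(resp)
  }
  list(cardiac = card, respiration = resp)
}

#' Condition indicator regressors at TR resolution
#'
#' Difficulty is a per-run constant indicator (hard = 1, easy = 0);
#' accuracy is a per-trial piecewise-constant indicator over each trial
#' window (incorrect = 1, correct = 0, lapse windows = 0).  A companion
#' `lapse` indicator flags lapse-trial windows.
#'
#' @param behavior behavior table.
#' @param n_volumes total number of fMRI volumes.
#' @param tr_s sampling interval.
#' @param protocol a [protocol_params()].
#' @return list with numeric vectors `difficulty`, `accuracy`, `lapse`.
#' @export
build_condition_regressors <- function(behavior, n_volumes, tr_s = 1.5,
                                       protocol = protocol_params()) {
  runs <- sort(unique(behavior$run_id))
  vol_per_run <- round(protocol$run_duration_s / tr_s)
  vol_per_trial <- round(protocol$trial_duration_s / tr_s)
  difficulty <- accuracy <- lapse <- numeric(n_volumes)
  for (ri in seq_along(runs)) {
    off <- (ri - 1) * vol_per_run
    sel <- which(behavior$run_id == runs[ri])
    difficulty[off + seq_len(vol_per_run)] <-
      as.numeric(behavior$difficulty[sel[1]] == "hard")
    for (k in sel) {
      i0 <- off + behavior$trial_index[k] * vol_per_trial + 1
      idx <- i0:min(i0 + vol_per_trial - 1, n_volumes)
      if (is.na(behavior$correct[k])) lapse[idx] <- 1
      else if (behavior$correct[k] == 0) accuracy[idx] <- 1
    }
  }
  list(difficulty = difficulty[seq_len(n_volumes)],
       accuracy = accuracy[seq_len(n_volumes)],
       lapse = lapse[seq_len(n_volumes)])
}

#' Assemble the fixed-effects design matrix
#'
#' Columns: intercept, the three HRF-convolved task inputs (decimated to
#' TR), difficulty, accuracy, cardiac and respiration predicted-BOLD
#' regressors, six motion traces, and the factorial interactions
#' task x difficulty (3), task x accuracy (3), difficulty x accuracy (1)
#' and task x difficulty x accuracy (3) formed as elementwise products -
#' 24 fixed-effect columns in total (18 without motion).
#'
#' @param task a `task_regressors` object (working-rate columns).
#' @param condition list from [build_condition_regressors()].
#' @param physio list with `cardiac`/`respiration` columns at TR, or NULL.
#' @param motion matrix with 6 columns at TR, or NULL to omit.
#' @param tr_s fMRI sampling interval.
#' @return a `design_matrix`: numeric matrix with unique column labels and
#'   attributes `tr_s` and (when rank-deficient) `rank_warning`.
#' @export
assemble_design <- function(task, condition, physio = NULL, motion = NULL,
                            tr_s = 1.5) {
  stopifnot(inherits(task, "task_regressors"))
  dec <- function(v) decimate(sampled_signal(v, task$working_rate_hz), 1 / tr_s)$values
  run_len <- task$run_len
  per_run <- function(v) {
    runs <- split(v, rep(seq_len(length(v) / run_len), each = run_len))
    unlist(lapply(runs, dec), use.names = FALSE)
  }
  TO <- per_run(task$fMRI_TO); BP <- per_run(task$fMRI_BP)
  ToT <- per_run(task$fMRI_ToT)
  n <- length(TO)
  chk <- function(v, nm) {
    if (length(v) != n) stop("length mismatch in column ", nm)
    v
  }
  cols <- list(intercept = rep(1, n), fMRI_TO = TO, fMRI_BP = BP, fMRI_ToT = ToT,
               difficulty = chk(condition$difficulty, "difficulty"),
               accuracy = chk(condition$accuracy, "accuracy"))
  if (!is.null(physio)) {
    cols$cardiac <- chk(physio$cardiac, "cardiac")
    cols$respiration <- chk(physio$respiration, "respiration")
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6) stop("motion must have 6 columns")
    mn <- colnames(motion)
    if (is.null(mn)) mn <- c("roll", "pitch", "yaw", "x", "y", "z")
    for (j in seq_len(6)) cols[[paste0("motion_", mn[j])]] <- chk(motion[, j], mn[j])
  }
  tasks <- list(fMRI_TO = TO, fMRI_BP = BP, fMRI_ToT = ToT)
  for (nm in names(tasks)) cols[[paste0(nm, ":difficulty")]] <-
    tasks[[nm]] * condition$difficulty
  for (nm in names(tasks)) cols[[paste0(nm, ":accuracy")]] <-
    tasks[[nm]] * condition$accuracy
  cols[["difficulty:accuracy"]] <- condition$difficulty * condition$accuracy
  for (nm in names(tasks)) cols[[paste0(nm, ":difficulty:accuracy")]] <-
    tasks[[nm]] * condition$difficulty * condition$accuracy

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyDuplicated(colnames(X))) stop("duplicate column labels")
  if (!all(is.finite(X))) stop("non-finite values in design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design is rank deficient; offending columns: ",
            paste(bad, collapse = ", "))
    attr(X, "rank_warning") <- bad
  }
  attr(X, "tr_s") <- tr_s
  class(X) <- c("design_matrix", class(X))
  X
}
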