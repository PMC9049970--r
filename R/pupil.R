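#' Interpolate over blink spans
#'
#' Samples inside each span, padded by `margin_s` on both sides, are
#' replaced by piecewise-cubic (spline) interpolation through the flanking
#' samples.  Spans touching the trace boundary are filled by
#' nearest-value extension with a warning.  NA samples outside declared
#' spans are treated as additional blink samples.
#'
#' @param trace a [sampled_signal()] (may contain NA inside spans).
#' @param missing_spans two-column matrix (start, end) in seconds.
#' @param margin_s padding margin per side, seconds.
#' @return a [sampled_signal()] with no missing values.
#' @export
deblink <- function(trace, missing_spans, margin_s = 0.1) {
  stopifnot(inherits(trace, "sampled_signal"))
  x <- trace$values
  tt <- signal_times(trace)
  bad <- is.na(x)
  if (!is.null(missing_spans) && length(missing_spans) > 0) {
    missing_spans <- matrix(as.numeric(missing_spans), ncol = 2)
    for (b in seq_len(nrow(missing_spans)))
      bad <- bad | (tt >= missing_spans[b, 1] - margin_s &
                    tt <= missing_spans[b, 2] + margin_s)
  }
  if (!any(bad)) return(trace)
  if (all(bad)) stop("no valid samples to interpolate from")
  good <- which(!bad)
  if (bad[1] || bad[length(x)]) {
    warning("blink span touches the trace boundary; extending nearest value")
  }
  fn <- stats::splinefun(tt[good], x[good], method = "fmm")
  y <- x
  inner <- which(bad & tt >= tt[good[1]] & tt <= tt[good[length(good)]])
  y[inner] <- fn(tt[inner])
  y[bad & tt < tt[good[1]]] <- x[good[1]]
  y[bad & tt > tt[good[length(good)]]] <- x[good[length(good)]]
  set_values(trace, y)
}

#' Band-pass filter specification for pupil traces
#' @param low_cut_hz,high_cut_hz band edges in Hz.
#' @param order Butterworth order per pass.
#' @return a `pupil_filter_spec` list (`zero_phase` is always TRUE).
#' @export
pupil_filter_spec <- function(low_cut_hz = 0.03, high_cut_hz = 10, order = 4) {
  if (!(0 < low_cut_hz && low_cut_hz < high_cut_hz))
    stop("need 0 < low_cut_hz < high_cut_hz")
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = order, zero_phase = TRUE),
            class = "pupil_filter_spec")
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the squared magnitude response of an `order`-th order Butterworth
#' high-pass at `low_cut_hz` cascaded with an `order`-th order low-pass at
#' `high_cut_hz` (the magnitude of a forward-backward filtfilt pass) in the
#' frequency domain, giving exactly zero phase.  DC is removed entirely.
#'
#' @param trace a [sampled_signal()] with finite values.
#' @param spec a [pupil_filter_spec()].
#' @return a filtered [sampled_signal()].
#' @export
bandpass <- function(trace, spec = pupil_filter_spec()) {
  stopifnot(inherits(trace, "sampled_signal"), inherits(spec, "pupil_filter_spec"))
  if (!all(is.finite(trace$values))) stop("trace contains non-finite values")
  if (spec$high_cut_hz >= trace$rate_hz / 2)
    stop("high cutoff at or above Nyquist")
  m <- 2 * spec$order                       # |H|^2 exponent per edge
  gain <- function(f) {
    g <- 1 / ((1 + (spec$low_cut_hz / pmax(f, 1e-12))^m) *
              (1 + (f / spec$high_cut_hz)^m))
    g[f == 0] <- 0
    g
  }
  set_values(trace, fft_filter(trace$values, trace$rate_hz, gain))
}

#' Task-evoked pupil response by condition
#'
#' Epochs the trace at trial onsets, averages by condition
#' (difficulty x accuracy), and reports the response amplitude as the
#' standard deviation of the condition-mean time course (default) or the
#' mean of per-trial standard deviations.
#'
#' @param trace a preprocessed [sampled_signal()].
#' @param behavior behavior table (pupil-protocol timing).
#' @param protocol a [protocol_params()] matching the behavior timing.
#' @param window_s epoch window from trial onset, seconds.
#' @param per_trial when TRUE amplitude is the mean of per-trial stds.
#' @return list per condition label with `mean` (time course), `amplitude`
#'   and `n`; conditions with no trials are absent.
#' @export
evoked_response <- function(trace, behavior, protocol, window_s = NULL,
                            per_trial = FALSE) {
  stopifnot(inherits(trace, "sampled_signal"))
  if (is.null(window_s)) window_s <- protocol$trial_duration_s
  nsamp <- round(window_s * trace$rate_hz)
  runs <- sort(unique(behavior$run_id))
  onset_abs <- (match(behavior$run_id, runs) - 1) * protocol$run_duration_s +
    behavior$onset_s
  i0 <- round(onset_abs * trace$rate_hz) + 1
  keep <- i0 + nsamp - 1 <= length(trace$values)
  epochs <- t(sapply(which(keep), function(k) trace$values[i0[k]:(i0[k] + nsamp - 1)]))
  cond <- trial_condition(behavior$difficulty, behavior$correct)[keep]
  out <- list()
  for (cc in unique(cond)) {
    rows <- epochs[cond == cc, , drop = FALSE]
    mu <- colMeans(rows)
    amp <- if (per_trial) mean(apply(rows, 1, stats::sd)) else stats::sd(mu)
    out[[cc]] <- list(mean = mu, amplitude = amp, n = nrow(rows))
  }
  out
}

#' Fixation stability per trial
#'
#' Standard deviation over time, within each trial window, of the Euclidean
#' distance between gaze and the fixation point.
#'
#' @param gaze_xy two-column matrix of gaze positions in degrees.
#' @param behavior behavior table.
#' @param protocol a [protocol_params()] matching the behavior timing.
#' @param rate_hz gaze sampling rate.
#' @param fixation fixation point, degrees (default origin).
#' @return numeric vector, one value per behavior row (NA when the trial
#'   window is empty).
#' @export
fixation_stability <- function(gaze_xy, behavior, protocol, rate_hz = 500,
                               fixation = c(0, 0)) {
  gaze_xy <- as.matrix(gaze_xy)
  d <- sqrt((gaze_xy[, 1] - fixation[1])^2 + (gaze_xy[, 2] - fixation[2])^2)
  runs <- sort(unique(behavior$run_id))
  onset_abs <- (match(behavior$run_id, runs) - 1) * protocol$run_duration_s +
    behavior$onset_s
  out <- rep(NA_real_, nrow(behavior))
  for (k in seq_len(nrow(behavior))) {
    i0 <- round(onset_abs[k] * rate_hz) + 1
    i1 <- min(round((onset_abs[k] + protocol$trial_duration_s) * rate_hz),
              length(d))
    if (i1 > i0) out[k] <- stats::sd(d[i0:i1])
  }
  out
}
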