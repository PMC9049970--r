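#' Sub-sample refinement of pulse peak times
#'
#' Candidate peaks are local maxima above an adaptive threshold
#' (median + 0.5 x IQR of the trace).  Each candidate is refined to the
#' intersection of a line fit to `k` rising-flank samples and a line fit to
#' `k` falling-flank samples (apex sample excluded), recovering peak times
#' lost to temporal undersampling.  Refined times falling more than one
#' sample period from the candidate, or degenerate (equal-slope) flank
#' fits, fall back to the candidate sample time.
#'
#' @param trace a [sampled_signal()] (>= 5 samples).
#' @param k flank samples per side used in each line fit.
#' @param min_sep_s minimum separation between peaks in seconds; of two
#'   candidates closer than this, the taller one is kept.
#' @return numeric vector of peak times in seconds (possibly empty).
#' @export
refine_peaks <- function(trace, k = 3, min_sep_s = 0.25) {
  stopifnot(inherits(trace, "sampled_signal"))
  x <- trace$values
  n <- length(x)
  if (n < 5) stop("trace too short")
  if (stats::sd(x) < 1e-12) return(numeric(0))
  thr <- stats::median(x) + 0.5 * stats::IQR(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] > thr]
  if (length(cand) == 0) return(numeric(0))
  min_sep <- round(min_sep_s * trace$rate_hz)
  if (min_sep > 0 && length(cand) > 1) {      # taller-peak suppression
    keep <- logical(length(cand))
    for (j in order(x[cand], decreasing = TRUE)) {
      if (!any(keep & abs(cand - cand[j]) < min_sep)) keep[j] <- TRUE
    }
    cand <- sort(cand[keep])
  }
  dt <- 1 / trace$rate_hz
  tt <- signal_times(trace)
  out <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    out[j] <- tt[i]
    if (i - k - 1 < 1 || i + k + 1 > n) next
    # place the flank windows symmetrically about the likely apex: when the
    # apex falls between samples the two apex-adjacent samples are nearly
    # equal and both are excluded from the fits
    dlr <- x[i + 1] - x[i - 1]
    curv <- 2 * x[i] - x[i - 1] - x[i + 1]
    if (abs(dlr) <= 0.25 * max(curv, 1e-12)) {      # apex ~ at the sample
      li <- (i - k):(i - 1); ri <- (i + 1):(i + k)
    } else if (dlr > 0) {                           # apex in (i, i+1)
      li <- (i - k):(i - 1); ri <- (i + 2):(i + k + 1)
    } else {                                        # apex in (i-1, i)
      li <- (i - k - 1):(i - 2); ri <- (i + 1):(i + k)
    }
    lf <- stats::lm.fit(cbind(1, tt[li]), x[li])$coefficients
    rf <- stats::lm.fit(cbind(1, tt[ri]), x[ri])$coefficients
    if (!all(is.finite(c(lf, rf))) || abs(lf[2] - rf[2]) < 1e-12) {
      warning("equal flank slopes; using candidate sample time")
      next
    }
    t_star <- (rf[1] - lf[1]) / (lf[2] - rf[2])
    if (abs(t_star - tt[i]) <= dt) out[j] <- t_star
  }
  out
}

#' Cardiac metrics in trial bins
#'
#' Per bin: heart rate = 60 / mean inter-beat interval (IBI); heart rate
#' variability = RMSSD of the IBIs; heart rate acceleration = mean of the
#' first differences of instantaneous rate (beats/s) divided by the elapsed
#' time between intervals, so positive values reflect a speeding heart.
#' Bins with fewer than 3 peaks yield missing values.
#'
#' @param peak_times beat times in seconds (e.g. from [refine_peaks()]).
#' @param bins two-column matrix (start, end) of trial windows in seconds.
#' @return data.frame with `hr_bpm`, `hrv_rmssd`, `hr_accel` per bin.
#' @export
pulse_metrics <- function(peak_times, bins) {
  bins <- as.matrix(bins)
  out <- data.frame(hr_bpm = rep(NA_real_, nrow(bins)),
                    hrv_rmssd = NA_real_, hr_accel = NA_real_)
  for (b in seq_len(nrow(bins))) {
    p <- peak_times[peak_times >= bins[b, 1] & peak_times < bins[b, 2]]
    if (length(p) < 3) next
    ibi <- diff(p)
    out$hr_bpm[b] <- 60 / mean(ibi)
    d <- diff(ibi)
    out$hrv_rmssd[b] <- sqrt(mean(d^2))
    rate <- 1 / ibi                              # beats per second
    elapsed <- (ibi[-length(ibi)] + ibi[-1]) / 2
    out$hr_accel[b] <- mean(diff(rate) / elapsed)
  }
  out
}

#' Respiration metrics in trial bins
#'
#' Per bin: volume = standard deviation of the percent-signal-change trace;
#' frequency = non-DC Fourier amplitude peak; variability = RMSSD of
#' peak-to-peak intervals from unrefined local maxima.  Bins too short to
#' contain a full breath yield missing values.
#'
#' @param trace a [sampled_signal()] respiration trace (percent change).
#' @param bins two-column matrix (start, end) of trial windows in seconds.
#' @return data.frame with `volume`, `frequency`, `variability` per bin.
#' @export
respiration_metrics <- function(trace, bins) {
  stopifnot(inherits(trace, "sampled_signal"))
  bins <- as.matrix(bins)
  tt <- signal_times(trace)
  out <- data.frame(volume = rep(NA_real_, nrow(bins)),
                    frequency = NA_real_, variability = NA_real_)
  for (b in seq_len(nrow(bins))) {
    idx <- which(tt >= bins[b, 1] & tt < bins[b, 2])
    if (length(idx) < 3) next
    x <- trace$values[idx]
    seg <- sampled_signal(x, trace$rate_hz)
    pk <- spectrum_peak(seg)
    if ((bins[b, 2] - bins[b, 1]) < 1 / pk$frequency) next
    out$volume[b] <- stats::sd(x)
    out$frequency[b] <- pk$frequency
    n <- length(x)
    loc <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
    if (length(loc) >= 3) {
      iv <- diff(tt[idx][loc])
      out$variability[b] <- if (length(iv) >= 2) sqrt(mean(diff(iv)^2)) else NA_real_
    }
  }
  out
}

#' Trial windows of a behavioral session
#'
#' 15-s bins, one per trial, in absolute session time (runs concatenated).
#'
#' @param behavior behavior table.
#' @param protocol a [protocol_params()].
#' @return two-column matrix (start, end) with one row per behavior row.
#' @export
trial_bins <- function(behavior, protocol = protocol_params()) {
  runs <- sort(unique(behavior$run_id))
  start <- (match(behavior$run_id, runs) - 1) * protocol$run_duration_s +
    behavior$onset_s
  cbind(start = start, end = start + protocol$trial_duration_s)
}
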