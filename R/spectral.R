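#' Least-squares sinusoid fit at a fixed frequency
#'
#' Fits a*cos(2 pi f t) + b*sin(2 pi f t) + intercept by ordinary least
#' squares.  Amplitude is sqrt(a^2 + b^2); phase is atan2(b, a), i.e. the
#' phi in A*cos(2 pi f t - phi), mapped to [0, 2 pi).
#'
#' @param series a [sampled_signal()] covering at least one cycle of `f`.
#' @param f frequency in Hz, below the Nyquist rate.
#' @return list with `amplitude` and `phase`.
#' @export
sinusoid_fit <- function(series, f) {
  stopifnot(inherits(series, "sampled_signal"))
  if (f >= series$rate_hz / 2) stop("f must be below the Nyquist frequency")
  tt <- signal_times(series)
  if (diff(range(tt)) < 1 / f) stop("series shorter than one cycle of f")
  X <- cbind(1, cos(2 * pi * f * tt), sin(2 * pi * f * tt))
  cf <- stats::lm.fit(X, series$values)$coefficients
  a <- cf[2]; b <- cf[3]
  list(amplitude = unname(sqrt(a^2 + b^2)),
       phase = unname(atan2(b, a) %% (2 * pi)))
}

#' Peak of the discrete Fourier amplitude spectrum
#'
#' @param series a [sampled_signal()] of length >= 2.
#' @return list with `frequency` (Hz, argmax over non-DC bins up to
#'   Nyquist) and `amplitude` (2/N x |DFT| at that bin).
#' @export
spectrum_peak <- function(series) {
  stopifnot(inherits(series, "sampled_signal"))
  x <- series$values
  n <- length(x)
  if (n < 2) stop("series too short")
  amp <- 2 * Mod(stats::fft(x)) / n
  nbins <- floor(n / 2)
  k <- which.max(amp[2:(nbins + 1)])       # skip DC
  list(frequency = k * series$rate_hz / n, amplitude = amp[k + 1])
}

#' Angular deviation of a phase sample
#'
#' s = sqrt(2 (1 - R)) with R the mean resultant length; 0 when all phases
#' are equal and sqrt(2) when the phases are uniformly distributed.
#'
#' @param phases radians.
#' @return list with `R` and `s`.
#' @export
angular_deviation <- function(phases) {
  if (length(phases) == 0) return(list(R = NA_real_, s = NA_real_))
  R <- Mod(mean(exp(1i * phases)))
  list(R = R, s = sqrt(2 * (1 - R)))
}

#' Per-trial amplitude, phase and temporal variability
#'
#' For each epoch row: amplitude = sample standard deviation of the
#' within-trial time course; phase = phase of the single-cycle (first
#' harmonic) discrete Fourier component of the mean-removed row, in
#' [0, 2 pi).  Temporal variability across trials is the angular deviation
#' s = sqrt(2 (1 - R)) of the phases.  Constant rows have no defined phase
#' and are excluded from R and s with a warning.
#'
#' @param epochs an `epoch_matrix` from [clean_and_epoch()].
#' @return list of class `spectral_summary`: `f_task`, `amplitude` and
#'   `phase` (per trial), `R`, `temporal_variability`.
#' @export
trial_metrics <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  m <- epochs$data
  if (nrow(m) < 1) stop("no trials")
  nsamp <- ncol(m)
  amp <- apply(m, 1, stats::sd)
  ph <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    row <- m[i, ] - mean(m[i, ])
    if (stats::sd(row) < 1e-14) next
    co <- stats::fft(row)[2]                 # one cycle per epoch
    ph[i] <- Arg(co) %% (2 * pi)
  }
  if (anyNA(ph)) warning("constant trial rows excluded from phase statistics")
  ad <- angular_deviation(ph[!is.na(ph)])
  structure(list(f_task = 1 / (nsamp * epochs$tr_s), amplitude = amp,
                 phase = ph, R = ad$R, temporal_variability = ad$s),
            class = "spectral_summary")
}

#' Response amplitude as max minus min
#' @param avg_response numeric vector (e.g. a trial-averaged time course).
#' @return max(avg_response) - min(avg_response).
#' @export
response_range <- function(avg_response) {
  if (length(avg_response) == 0) stop("empty input")
  max(avg_response) - min(avg_response)
}
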