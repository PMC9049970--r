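#' Uniformly sampled one-dimensional signal
#'
#' Lightweight container used throughout the package for BOLD, pulse,
#' respiration, head-motion and pupil traces: a numeric vector together with
#' its sampling rate, start time and units.
#'
#' @param values numeric vector of samples.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param start_s time of the first sample in seconds.
#' @param units character label for the sample units (e.g. "psc" for percent
#'   signal change, "a.u." for arbitrary units).
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, rate_hz, start_s = 0, units = "a.u.") {
  if (!is.numeric(values)) stop("values must be numeric")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a positive scalar")
  structure(
    list(values = as.numeric(values), rate_hz = as.numeric(rate_hz),
         start_s = as.numeric(start_s), units = as.character(units)),
    class = "sampled_signal"
  )
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Sample times of a signal
#' @param x a `sampled_signal`.
#' @return numeric vector of times (seconds) for each sample.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$start_s + seq_along(x$values) / x$rate_hz - 1 / x$rate_hz
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %.4g Hz, start %.3f s [%s]\n",
              length(x$values), x$rate_hz, x$start_s, x$units))
  invisible(x)
}

# internal: replace the value vector, keeping metadata
set_values <- function(x, values, units = x$units) {
  sampled_signal(values, x$rate_hz, x$start_s, units)
}
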