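#' Run a one-up/two-down adaptive staircase
#'
#' Simulates `n_trials` staircase trials for a stochastic observer.  After
#' two consecutive correct responses the tilt magnitude decreases by one
#' step; after every incorrect response it increases by one step; tilts are
#' clamped to `[min_tilt_deg, max_tilt_deg]`.  The asymptotic percent
#' correct converges to the 1-up-2-down fixed point sqrt(1/2) (~70.7%)
#' whenever the observer's ceiling accuracy exceeds it.
#'
#' @param spec a [staircase_spec()].
#' @param observer an [observer_model()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer RNG seed; the run is deterministic given the seed.
#' @return data.frame with columns `tilt_deg` (magnitude presented) and
#'   `correct` (0/1).
#' @export
run_staircase <- function(spec, observer, n_trials, seed = 1L) {
  stopifnot(inherits(spec, "staircase_spec"), inherits(observer, "observer_model"))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tilt <- spec$initial_tilt_deg
  tilts <- numeric(n_trials)
  correct <- integer(n_trials)
  streak <- 0L
  u <- stats::runif(n_trials)
  for (i in seq_len(n_trials)) {
    tilts[i] <- tilt
    ok <- u[i] < p_correct(observer, tilt)
    correct[i] <- as.integer(ok)
    if (ok) {
      streak <- streak + 1L
      if (streak >= spec$n_down) {
        tilt <- max(spec$min_tilt_deg, tilt - spec$step_deg)
        streak <- 0L
      }
    } else {
      tilt <- min(spec$max_tilt_deg, tilt + spec$step_deg)
      streak <- 0L
    }
  }
  data.frame(tilt_deg = tilts, correct = correct)
}

# Save/restore .Random.seed so seeded generators do not clobber the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
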