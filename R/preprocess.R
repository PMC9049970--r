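#' Convert a series to percent signal change
#'
#' 100 * (x - mean) / mean, computed per run when `run_len` is given.
#'
#' @param signal a [sampled_signal()].
#' @param run_len samples per run; NULL treats the whole series as one run.
#' @return a [sampled_signal()] in percent-signal-change units.
#' @export
percent_change <- function(signal, run_len = NULL) {
  stopifnot(inherits(signal, "sampled_signal"))
  x <- signal$values
  if (is.null(run_len)) run_len <- length(x)
  out <- unlist(lapply(split(x, rep(seq_len(length(x) / run_len), each = run_len)),
                       function(v) {
                         m <- mean(v)
                         if (abs(m) < 1e-12) stop("zero-mean run: percent change undefined")
                         100 * (v - m) / m
                       }), use.names = FALSE)
  set_values(signal, out, units = "psc")
}

#' Global (mean across voxels) signal
#' @param voxels a `voxel_signals` object or a voxel-by-time matrix.
#' @return a [sampled_signal()] (or numeric vector for matrix input).
#' @export
global_signal <- function(voxels) {
  m <- if (inherits(voxels, "voxel_signals")) voxels$voxels else as.matrix(voxels)
  if (nrow(m) < 1 || ncol(m) < 1) stop("empty voxel collection")
  g <- colMeans(m)
  if (inherits(voxels, "voxel_signals"))
    sampled_signal(g, 1 / voxels$tr_s, 0, "psc") else g
}

#' Average voxels over a region of interest
#' @param voxels a `voxel_signals` object or voxel-by-time matrix.
#' @param roi_mask integer or logical index over voxels (rows).
#' @return a [sampled_signal()] (or numeric vector for matrix input).
#' @export
roi_average <- function(voxels, roi_mask) {
  m <- if (inherits(voxels, "voxel_signals")) voxels$voxels else as.matrix(voxels)
  sub <- m[roi_mask, , drop = FALSE]
  if (nrow(sub) < 1) stop("empty ROI mask")
  g <- colMeans(sub)
  if (inherits(voxels, "voxel_signals"))
    sampled_signal(g, 1 / voxels$tr_s, 0, "psc") else g
}

#' Project nuisance components out of a series
#'
#' Least-squares residual of the series on an intercept plus the nuisance
#' columns, with the series mean added back so percent-change units are
#' preserved.  Collinear nuisance columns are dropped with a warning.
#' Performed per run when `run_len` is given (runs are independent
#' acquisitions).
#'
#' @param series a [sampled_signal()].
#' @param nuisance numeric vector or matrix of nuisance columns.
#' @param run_len samples per run; NULL treats the series as one run.
#' @return a [sampled_signal()]; the residual is orthogonal to every
#'   retained nuisance column within each run.
#' @export
project_out <- function(series, nuisance, run_len = NULL) {
  stopifnot(inherits(series, "sampled_signal"))
  y <- series$values
  N <- as.matrix(nuisance)
  if (nrow(N) != length(y)) stop("series and nuisance lengths differ")
  if (is.null(run_len)) run_len <- length(y)
  grp <- rep(seq_len(length(y) / run_len), each = run_len)
  out <- numeric(length(y))
  for (g in unique(grp)) {
    i <- which(grp == g)
    X <- cbind(1, N[i, , drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      warning("rank-deficient nuisance set; dropping collinear columns")
      X <- X[, keep, drop = FALSE]
    }
    res <- stats::lm.fit(X, y[i])$residuals
    out[i] <- res + mean(y[i])
  }
  set_values(series, out)
}

#' Epoch a series into trials and apply exclusion rules
#'
#' Cuts the series into per-trial rows of `trial_duration_s / tr_s` samples,
#' removes the first trial of every run, and partitions the remaining rows
#' into response trials and lapse trials.
#'
#' @param series a [sampled_signal()] at TR covering all trials.
#' @param behavior behavior table aligned with the series.
#' @param protocol a [protocol_params()].
#' @return list of two `epoch_matrix` objects, `responses` and `lapses`;
#'   each is a list with `data` (trials x samples matrix), `meta`
#'   (difficulty, accuracy, rt, lapse, run_id, trial_index) and `tr_s`.
#' @export
clean_and_epoch <- function(series, behavior, protocol = protocol_params()) {
  stopifnot(inherits(series, "sampled_signal"))
  tr_s <- 1 / series$rate_hz
  spt <- round(protocol$trial_duration_s / tr_s)     # samples per trial
  vol_per_run <- round(protocol$run_duration_s / tr_s)
  runs <- sort(unique(behavior$run_id))
  n_expected <- length(runs) * vol_per_run
  if (length(series$values) < n_expected)
    stop("series shorter than the behavioral session")

  rows <- list(); meta <- list()
  for (k in seq_len(nrow(behavior))) {
    ri <- match(behavior$run_id[k], runs)
    i0 <- (ri - 1) * vol_per_run + behavior$trial_index[k] * spt + 1
    rows[[k]] <- series$values[i0:(i0 + spt - 1)]
    meta[[k]] <- data.frame(run_id = behavior$run_id[k],
                            trial_index = behavior$trial_index[k],
                            difficulty = behavior$difficulty[k],
                            correct = behavior$correct[k],
                            rt_s = behavior$rt_s[k],
                            lapse = is.na(behavior$correct[k]))
  }
  mat <- do.call(rbind, rows)
  md <- do.call(rbind, meta)
  keep <- md$trial_index != 0                        # first trial of each run
  mat <- mat[keep, , drop = FALSE]; md <- md[keep, , drop = FALSE]
  mk <- function(sel) structure(list(data = mat[sel, , drop = FALSE],
                                     meta = md[sel, , drop = FALSE],
                                     tr_s = tr_s),
                                class = "epoch_matrix")
  list(responses = mk(!md$lapse), lapses = mk(md$lapse))
}

#' Full ROI preprocessing pipeline
#'
#' Fixed order: percent-change scaling is assumed done by the generator
#' (series already in psc); per-run global-signal projection from each
#' voxel, then physiological/motion projection, then ROI averaging, then
#' epoching with trial-exclusion rules.
#'
#' @param bold a `voxel_signals` object.
#' @param behavior behavior table.
#' @param protocol a [protocol_params()].
#' @param roi_mask voxel indices for the ROI (default: the simulation's
#'   `roi_mask`, else all voxels).
#' @param nuisance optional matrix of additional nuisance columns at TR
#'   (physiological predictors, motion).
#' @return list with `roi` (the cleaned ROI [sampled_signal()]) and the
#'   epoch partitions from [clean_and_epoch()].
#' @export
preprocess_roi <- function(bold, behavior, protocol = protocol_params(),
                           roi_mask = NULL, nuisance = NULL) {
  stopifnot(inherits(bold, "voxel_signals"))
  if (is.null(roi_mask))
    roi_mask <- if (!is.null(bold$roi_mask)) bold$roi_mask
                else seq_len(nrow(bold$voxels))
  run_len <- round(protocol$run_duration_s / protocol$tr_s)
  gs <- global_signal(bold)
  cleaned <- bold$voxels[roi_mask, , drop = FALSE]
  for (v in seq_len(nrow(cleaned))) {
    s <- sampled_signal(cleaned[v, ], 1 / bold$tr_s, 0, "psc")
    s <- project_out(s, gs$values, run_len = run_len)
    if (!is.null(nuisance)) s <- project_out(s, nuisance, run_len = run_len)
    cleaned[v, ] <- s$values
  }
  roi <- sampled_signal(colMeans(cleaned), 1 / bold$tr_s, 0, "psc")
  c(list(roi = roi), clean_and_epoch(roi, behavior, protocol))
}
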