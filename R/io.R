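#' Write a behavior table as a BIDS-style events TSV
#'
#' Columns: onset, duration, trial_type, response_time, correct, difficulty,
#' run (plus observer and tilt).  Missing response times and accuracies are
#' written as "n/a".
#'
#' @param behavior behavior table.
#' @param path output file path.
#' @param stim_duration_s stimulus duration written to `duration`.
#' @return the path, invisibly.
#' @export
write_events <- function(behavior, path, stim_duration_s = 0.2) {
  df <- data.frame(
    onset = behavior$onset_s, duration = stim_duration_s,
    trial_type = trial_condition(behavior$difficulty, behavior$correct),
    response_time = ifelse(is.na(behavior$rt_s), "n/a", behavior$rt_s),
    correct = ifelse(is.na(behavior$correct), "n/a", behavior$correct),
    difficulty = behavior$difficulty, run = behavior$run_id,
    observer = behavior$observer_id, tilt = behavior$tilt_deg,
    trial_index = behavior$trial_index
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV into a behavior table
#'
#' @param path TSV with columns onset, duration, trial_type, response_time,
#'   correct, difficulty, run.  "n/a" response times mark lapse trials.
#' @return behavior data.frame (see [simulate_behavior()]).
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("onset", "duration", "trial_type", "response_time", "correct",
            "difficulty", "run")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events file missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- function(v, col) {
    out <- suppressWarnings(as.numeric(ifelse(v %in% c("n/a", "NA", ""), NA, v)))
    bad <- which(!(v %in% c("n/a", "NA", "")) & is.na(out))
    if (length(bad)) stop("malformed value in column '", col, "' at line ",
                          bad[1] + 1)
    out
  }
  rt <- num(df$response_time, "response_time")
  behavior <- data.frame(
    observer_id = if ("observer" %in% names(df)) df$observer else "O1",
    run_id = as.integer(num(df$run, "run")),
    trial_index = if ("trial_index" %in% names(df))
      as.integer(num(df$trial_index, "trial_index"))
    else stats::ave(num(df$onset, "onset"), df$run,
                    FUN = function(x) rank(x) - 1),
    onset_s = num(df$onset, "onset"),
    difficulty = df$difficulty,
    tilt_deg = if ("tilt" %in% names(df)) num(df$tilt, "tilt") else NA_real_,
    response = ifelse(is.na(rt), "none", "cw"),
    correct = as.integer(num(df$correct, "correct")),
    rt_s = rt, stringsAsFactors = FALSE
  )
  lapse <- is.na(behavior$rt_s)
  behavior$correct[lapse] <- NA_integer_
  behavior$response[lapse] <- "none"
  behavior
}

#' Write a physiological trace as gzipped TSV with a JSON sidecar
#'
#' @param signal a [sampled_signal()].
#' @param path output path for the gzipped TSV (e.g. "pulse.tsv.gz"); the
#'   sidecar is written next to it with extension ".json".
#' @param columns column name(s) for the values.
#' @return the TSV path, invisibly.
#' @export
write_physio <- function(signal, path, columns = "value") {
  stopifnot(inherits(signal, "sampled_signal"))
  con <- gzfile(path, "wt")
  utils::write.table(data.frame(value = signal$values), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(SamplingFrequency = signal$rate_hz,
                            StartTime = signal$start_s,
                            Columns = as.list(columns),
                            Units = signal$units),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a physiological trace (gzipped TSV + JSON sidecar)
#'
#' @param path the gzipped TSV written by [write_physio()].
#' @return a [sampled_signal()] with rate and start from the sidecar.
#' @export
read_physio <- function(path) {
  sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$SamplingFrequency)) stop("sidecar lacks SamplingFrequency")
  v <- utils::read.table(gzfile(path), sep = "\t", header = FALSE)[[1]]
  if (length(v) == 0) stop("empty physiological trace")
  sampled_signal(v, meta$SamplingFrequency,
                 if (is.null(meta$StartTime)) 0 else meta$StartTime,
                 if (is.null(meta$Units)) "a.u." else meta$Units)
}

#' Write an epoch matrix as TSV (metadata columns then samples)
#' @param epochs an `epoch_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  samp <- as.data.frame(epochs$data)
  names(samp) <- sprintf("s%02d", seq_len(ncol(samp)))
  utils::write.table(cbind(epochs$meta, samp), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' JSON-backed configuration bundling protocol, generator, pipeline and
#' statistics settings.  Unspecified fields take the package defaults; the
#' configuration round-trips losslessly through [write_config()] /
#' [read_config()].
#'
#' @param protocol,observer,staircase,truth parameter lists overriding the
#'   defaults of the respective constructors.
#' @param n_observers,n_voxels session dimensions.
#' @param seed base RNG seed.
#' @param m permutations for the physiological tests.
#' @param alpha FDR level.
#' @return a `run_config` list.
#' @export
run_config <- function(protocol = list(), observer = list(), staircase = list(),
                       truth = list(), n_observers = 3, n_voxels = 10,
                       seed = 1, m = 1000, alpha = 0.05) {
  structure(list(protocol = protocol, observer = observer,
                 staircase = staircase, truth = truth,
                 n_observers = n_observers, n_voxels = n_voxels,
                 seed = seed, m = m, alpha = alpha),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Materialize constructor objects from a configuration
#' @param config a [run_config()].
#' @return list with `protocol`, `observer`, `staircase`, `truth` objects.
#' @export
config_objects <- function(config) {
  list(protocol = do.call(protocol_params, config$protocol),
       observer = do.call(observer_model, config$observer),
       staircase = do.call(staircase_spec, config$staircase),
       truth = do.call(ground_truth_spec, config$truth))
}
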