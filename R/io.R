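# CSV/JSON interchange for simulated experiments and pipeline results.

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column '%s'", what, missing[1]),
         call. = FALSE)
  }
  invisible(df)
}

PRESS_SCHEMA <- c("participant", "day", "block", "trial", "w", "position",
                  "target", "produced", "press_time_ms", "release_time_ms",
                  "stim_onset_ms")

#' Write and read a simulated experiment as plain-text files
#'
#' `write_experiment()` writes `trials.csv` (one row per press),
#' `calibration.csv`, optional `force.csv` / `eye.csv`, and a
#' `params_truth.json` sidecar holding the generative parameters and the
#' per-participant-per-day true model values. `read_experiment()` restores
#' the `"horizon_experiment"` object from such a directory.
#'
#' @param experiment a `"horizon_experiment"`.
#' @param dir output directory (created if needed).
#' @return `write_experiment()` the directory, invisibly;
#'   `read_experiment()` a `"horizon_experiment"`.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "horizon_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(experiment$presses, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$calibration, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  if (!is.null(experiment$force)) {
    utils::write.csv(experiment$force, file.path(dir, "force.csv"),
                     row.names = FALSE)
  }
  if (!is.null(experiment$eye)) {
    utils::write.csv(experiment$eye, file.path(dir, "eye.csv"),
                     row.names = FALSE)
  }
  sidecar <- list(params = unclass(experiment$params),
                  truth = experiment$truth)
  jsonlite::write_json(sidecar, file.path(dir, "params_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  presses <- utils::read.csv(file.path(dir, "trials.csv"))
  check_schema(presses, PRESS_SCHEMA, "trials.csv")
  side <- jsonlite::read_json(file.path(dir, "params_truth.json"),
                              simplifyVector = TRUE)
  params <- side$params
  params$window_set <- as.integer(params$window_set)
  params <- do.call(horizon_sim_params,
                    params[setdiff(names(params), "sr_time")])
  out <- list(
    presses = presses,
    truth = as.data.frame(side$truth),
    force = if (file.exists(file.path(dir, "force.csv")))
      utils::read.csv(file.path(dir, "force.csv")) else NULL,
    eye = if (file.exists(file.path(dir, "eye.csv")))
      utils::read.csv(file.path(dir, "eye.csv")) else NULL,
    calibration = utils::read.csv(file.path(dir, "calibration.csv")),
    params = params
  )
  class(out) <- "horizon_experiment"
  out
}
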