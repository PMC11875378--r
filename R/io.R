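#' Write per-trial results to CSV
#'
#' One row per trial: condition, delay, success flags, rt, srt.
#'
#' @param results Tidy trial tibble from [run_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Write trajectories to long-format CSV
#'
#' Columns `trial_id`, `t_ms`, `x_cm`, `y_cm`.
#'
#' @param trajectories List of trajectory data frames (e.g. the
#'   `"trajectories"` attribute of [run_experiment()] output).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    data.frame(trial_id = i, t_ms = tr$t_ms, x_cm = tr$x_cm, y_cm = tr$y_cm)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format trajectory CSV
#'
#' Inverse of [write_trajectories_csv()]; recorded joystick logs converted
#' to the `(trial_id, t_ms, x_cm, y_cm)` schema enter the analysis here.
#'
#' @param path CSV path.
#' @return Named list of per-trial trajectory data frames.
#' @export
read_trajectories_csv <- function(path) {
  d <- utils::read.csv(path)
  split(d[c("t_ms", "x_cm", "y_cm")], d$trial_id)
}

#' Write trial events as JSON Lines
#'
#' One line per event: `{"trial_id": ..., "event": ..., "t_ms": ...}`.
#'
#' @param events List (per trial) of named event-time lists.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    for (nm in names(ev)) {
      writeLines(jsonlite::toJSON(
        list(trial_id = i, event = nm, t_ms = ev[[nm]]),
        auto_unbox = TRUE
      ), con)
    }
  }
  invisible(path)
}

#' Export a planning-field activity trace to long-format CSV
#'
#' Columns `t_ms`, `neuron_index`, `u` — the layout used for field-activity
#' heatmaps.
#'
#' @param trace `steps x n` activity matrix (rows at each `dt`).
#' @param dt Step in ms.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_field_trace <- function(trace, dt, path) {
  d <- data.frame(
    t_ms = rep(seq_len(nrow(trace)) * dt, ncol(trace)),
    neuron_index = rep(seq_len(ncol(trace)), each = nrow(trace)),
    u = as.vector(trace)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
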