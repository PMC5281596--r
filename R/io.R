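#' Schedule serialization
#'
#' Trial schedules round-trip through a documented JSON layout: top-level
#' design metadata (`sequence_id`, `soa`, `deviant_category`) plus the
#' `events` and `task_events` tables and the originating session
#' configuration.
#'
#' @param schedule a `vmmn_schedule`.
#' @param path file path.
#' @return `read_schedule_json()` returns a `vmmn_schedule`;
#'   `write_schedule_json()` its path, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "vmmn_schedule"))
  payload <- list(
    sequence_id = schedule$sequence_id,
    soa = schedule$soa,
    deviant_category = schedule$deviant_category,
    standard_category = schedule$standard_category,
    config = unclass(schedule$config),
    events = schedule$events,
    task_events = schedule$task_events
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(session_config, payload$config[setdiff(
    names(payload$config), character(0)
  )])
  out <- list(
    sequence_id = payload$sequence_id,
    soa = payload$soa,
    deviant_category = payload$deviant_category,
    standard_category = payload$standard_category,
    config = cfg,
    events = as.data.frame(payload$events),
    task_events = as.data.frame(payload$task_events)
  )
  if (nrow(out$task_events) == 0) {
    out$task_events <- data.frame(onset = numeric(0), side = character(0),
                                  duration = numeric(0))
  }
  class(out) <- "vmmn_schedule"
  out
}

#' Recording serialization (internal array format)
#'
#' Recordings are stored in the package's internal array format (an RDS
#' container holding the samples x channels matrix, channel labels,
#' sampling rate and schedule), which round-trips exactly.
#'
#' @param recording a `vmmn_recording`.
#' @param path file path.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "vmmn_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  stopifnot(inherits(rec, "vmmn_recording"))
  rec
}

#' 2AFC response table CSV
#'
#' Header: `trial,soa_ms,letter_position,response,correct`.
#'
#' @param responses table from [generate_2afc_responses()].
#' @param path file path.
#' @export
write_2afc_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_2afc_csv
#' @export
read_2afc_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$correct <- as.logical(out$correct)
  out
}

#' Write a detection table
#'
#' Machine-readable summary of vMMN presence: one row per significant
#' window with columns `soa`, `group`, `stimulus`, `roi`,
#' `window_start_ms`, `window_end_ms`.
#'
#' @param detection_table data frame in that layout (see
#'   [run_experiment()]).
#' @param path file path (`.csv`).
#' @export
write_detection_table <- function(detection_table, path) {
  utils::write.csv(detection_table, path, row.names = FALSE)
  invisible(path)
}
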