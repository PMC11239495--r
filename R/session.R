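#' Session records: aligned multichannel physiological time series
#'
#' A session record is a tibble with one row per master-rate sample and
#' the canonical channel columns `time_s`, `glucose_mM`, `activity_z`,
#' `running_cms`, `vo2_lmin`, `vco2_lmin`, `temp_C`, plus an `events`
#' attribute (tibble of labelled event times, e.g. the infusion) and a
#' free-form `meta` attribute. It is the common currency all analysis
#' stages consume.
#'
#' @param data Data frame with the canonical columns.
#' @param events Tibble with at least `label` and `time_s` columns.
#' @param meta Named list of free-form metadata.
#' @return A `session_record` tibble.
#' @export
new_session_record <- function(data,
                               events = tibble(label = character(0),
                                               time_s = numeric(0)),
                               meta = list()) {
  data <- as_tibble(data)
  validate_session(data)
  attr(data, "events") <- as_tibble(events)
  attr(data, "meta") <- meta
  class(data) <- c("session_record", class(data))
  data
}

session_channels <- c("time_s", "glucose_mM", "activity_z", "running_cms",
                      "vo2_lmin", "vco2_lmin", "temp_C")

validate_session <- function(data) {
  missing <- setdiff(session_channels, names(data))
  if (length(missing) > 0L) {
    abort(paste0("session is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(diff(data$time_s) <= 0)) abort("time_s must be strictly increasing")
  if (anyNA(data[session_channels])) abort("session channels contain NA")
  invisible(data)
}

#' Event table of a session record
#' @param session A `session_record`.
#' @return Tibble of events (`label`, `time_s`, ...).
#' @export
session_events <- function(session) attr(session, "events")

# First infusion time of a session; errors if none recorded.
infusion_time_of <- function(session) {
  ev <- session_events(session)
  inf <- ev$time_s[ev$label == "infusion"]
  if (length(inf) == 0L) abort("session has no infusion event")
  inf[1L]
}

#' Read a session record from CSV plus JSON sidecar
#'
#' The CSV holds the canonical channel columns; the sidecar
#' (`<path without .csv>.json`, or `sidecar`) holds the event table and
#' metadata. Extra CSV columns are preserved in `meta$extra_columns`.
#'
#' @param path CSV path.
#' @param sidecar JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return A `session_record`.
#' @export
read_session <- function(path, sidecar = sub("\\.csv$", ".json", path)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(session_channels, names(data))
  if (length(missing) > 0L) {
    abort(paste0("session file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(data), session_channels)
  events <- tibble(label = character(0), time_s = numeric(0))
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$events)) events <- as_tibble(side$events)
    if (!is.null(side$meta)) meta <- side$meta
  }
  if (length(extra) > 0L) meta$extra_columns <- data[extra]
  new_session_record(data[session_channels], events = events, meta = meta)
}

#' Write a session record to CSV plus JSON sidecar
#'
#' @param session A `session_record`.
#' @param path CSV path; the sidecar goes to the same path with `.json`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  readr::write_csv(as_tibble(session)[session_channels], path)
  side <- list(events = session_events(session),
               meta = attr(session, "meta"))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write / read a cell-trace matrix as CSV
#'
#' Rows are cell-grid samples (first column `time_s`), remaining columns
#' one per cell ID.
#'
#' @param traces Matrix (rows = samples, columns = cells) with column
#'   names.
#' @param time Cell-grid times in seconds.
#' @param path CSV path.
#' @return `path` invisibly ([write_cells()]); a list `traces`, `time`
#'   ([read_cells()]).
#' @export
write_cells <- function(traces, time, path) {
  df <- as_tibble(as.data.frame(traces))
  df <- dplyr::bind_cols(tibble(time_s = time), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  list(traces = as.matrix(df[setdiff(names(df), "time_s")]),
       time = df$time_s)
}
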