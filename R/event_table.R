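#' Construct an event table
#'
#' An event table is the "flattened" form of a count sheet: one row per
#' individual worm, giving the day it left the assay and whether it died
#' (`DEATH`) or was censored (`CENSORED` -- missing, bagged, exploded, or
#' still alive when scoring ended). All downstream estimation and testing
#' consumes event tables.
#'
#' @param events Data frame with columns `condition` (character),
#'   `time` (positive days) and `status` (`"DEATH"` or `"CENSORED"`).
#' @inheritParams count_sheet
#' @return An object of class `event_table`: a list with a tibble `events`
#'   plus the experiment metadata (`control`, `experiment_name`,
#'   `temperature_c`, `researchers`, `colors`).
#' @export
event_table <- function(events, control, experiment_name = "lifespan",
                        temperature_c = NULL, researchers = NULL,
                        colors = NULL) {
  required <- c("condition", "time", "status")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    ws_error(
      paste0("event table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "wormspan_format_error"
    )
  }
  events <- tibble::as_tibble(events)[required]
  events$condition <- as.character(events$condition)
  events$time <- as.numeric(events$time)
  events$status <- as.character(events$status)
  bad_status <- setdiff(unique(events$status), c("DEATH", "CENSORED"))
  if (length(bad_status) > 0) {
    ws_error(
      sprintf("unrecognized status token(s): %s (accepted: DEATH, CENSORED)",
              paste(bad_status, collapse = ", ")),
      "wormspan_format_error"
    )
  }
  if (nrow(events) > 0 && any(!is.finite(events$time) | events$time <= 0)) {
    ws_error("event times must be positive numbers", "wormspan_validation_error")
  }
  events <- dplyr::arrange(events, .data$condition, .data$time, .data$status)
  structure(
    list(
      events = events,
      control = as.character(control),
      experiment_name = as.character(experiment_name),
      temperature_c = if (is.null(temperature_c)) NULL else as.numeric(temperature_c),
      researchers = if (is.null(researchers)) NULL else as.character(researchers),
      colors = colors
    ),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", x$experiment_name, "\n", sep = "")
  tab <- table(x$events$condition, factor(x$events$status, c("DEATH", "CENSORED")))
  cat("  control: ", x$control, "\n", sep = "")
  print(tab)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble event_table
#' @export
as_tibble.event_table <- function(x, ...) x$events

#' Flatten a count sheet to per-individual event records
#'
#' Expands each scored day into individual records: a row with `died = d` and
#' `censored = c` at day `t` becomes `d` `DEATH` records and `c` `CENSORED`
#' records at time `t`. Worms still alive at a condition's final observation
#' are emitted as `CENSORED` at that final day (end-of-assay censoring).
#' Deaths are assigned the day they were scored, not an interval midpoint.
#'
#' @param sheet A validated [count_sheet()].
#' @return An [event_table()] carrying the sheet's metadata. Per condition the
#'   number of records equals the initial number of worms, and records are
#'   sorted by condition, time, then status.
#' @export
#' @examples
#' sheet <- count_sheet(
#'   data.frame(condition = "N2", day = c(0, 5, 10),
#'              alive = c(10, 6, 0), died = c(0, 4, 5), censored = c(0, 0, 1)),
#'   control = "N2"
#' )
#' convert_counts(sheet)$events
convert_counts <- function(sheet) {
  validate_count_sheet(sheet)
  per_condition <- function(rows) {
    last_day <- rows$day[nrow(rows)]
    deaths <- rep(rows$day, times = rows$died)
    cens <- rep(rows$day, times = rows$censored)
    leftover <- rows$alive[nrow(rows)]
    cens <- c(cens, rep(last_day, leftover))
    tibble::tibble(
      time = c(deaths, cens),
      status = c(rep("DEATH", length(deaths)), rep("CENSORED", length(cens)))
    )
  }
  events <- sheet$data |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ per_condition(.x)) |>
    dplyr::ungroup()
  event_table(events,
              control = sheet$control,
              experiment_name = sheet$experiment_name,
              temperature_c = sheet$temperature_c,
              researchers = sheet$researchers,
              colors = sheet$colors)
}

#' Write an event table to CSV
#'
#' Writes `condition,time,status` rows preceded by `#key: value` metadata
#' comment lines, so [read_event_table()] round-trips the object exactly.
#'
#' @param table An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  meta <- c(
    paste0("#experiment: ", table$experiment_name),
    paste0("#control: ", table$control),
    if (!is.null(table$temperature_c)) paste0("#temperature_c: ", table$temperature_c),
    if (!is.null(table$researchers)) paste0("#researchers: ", paste(table$researchers, collapse = ", ")),
    if (!is.null(table$colors)) paste0("#color:", names(table$colors), "=", unname(table$colors))
  )
  body <- sub("\n$", "", readr::format_csv(table$events))
  ok <- tryCatch({
    writeLines(c(meta, body), path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    ws_error(sprintf("cannot write event table to '%s'", path), "wormspan_io_error")
  }
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path Path to a CSV written by [write_event_table()] (columns
#'   `condition,time,status`, optional `#key: value` metadata lines).
#' @param control Override the control label from the file metadata;
#'   required if the file carries none.
#' @return A validated [event_table()].
#' @export
read_event_table <- function(path, control = NULL) {
  if (!file.exists(path)) {
    ws_error(sprintf("event table file not found: %s", path), "wormspan_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0 || all(trimws(lines) == "")) {
    ws_error(sprintf("event table file is empty: %s", path), "wormspan_format_error")
  }
  meta <- parse_sheet_metadata(lines)
  events <- suppressWarnings(readr::read_csv(
    I(paste(lines, collapse = "\n")),
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      condition = readr::col_character(),
      status = readr::col_character(),
      .default = readr::col_double()
    )
  ))
  event_table(events,
              control = control %||% meta$control %||% NA_character_,
              experiment_name = meta$experiment_name %||%
                tools::file_path_sans_ext(basename(path)),
              temperature_c = meta$temperature_c,
              researchers = meta$researchers,
              colors = meta$colors)
}
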