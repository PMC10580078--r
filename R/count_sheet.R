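#' Construct a lifespan count sheet
#'
#' A count sheet is the in-memory form of a manually scored lifespan
#' spreadsheet: one row per condition per observation day, recording how many
#' worms are alive after that day's scoring and how many deaths and censoring
#' events (missing, bagged, exploded animals) were newly recorded that day.
#'
#' @param data A data frame with columns `condition`, `day`, `alive`, `died`,
#'   `censored`. Days within a condition must be strictly increasing and the
#'   bookkeeping identity `alive[k] = alive[k-1] - died[k] - censored[k]` must
#'   hold for consecutive rows of a condition.
#' @param control Label of the control condition; must appear in `data`.
#' @param experiment_name Name of the experiment (used for plot titles and
#'   output file names).
#' @param temperature_c Assay temperature in degrees Celsius, or `NULL`.
#' @param researchers Character vector of researcher initials, or `NULL`.
#' @param colors Named character vector mapping condition labels to colors,
#'   or `NULL` to use the default palette downstream.
#'
#' @return An object of class `count_sheet`: a list with elements `data`
#'   (a tibble), `control`, `experiment_name`, `temperature_c`,
#'   `researchers` and `colors`.
#' @seealso [read_count_sheet()], [convert_counts()]
#' @export
#' @examples
#' sheet <- count_sheet(
#'   data.frame(
#'     condition = "N2", day = c(0, 5, 10),
#'     alive = c(10, 6, 0), died = c(0, 4, 5), censored = c(0, 0, 1)
#'   ),
#'   control = "N2"
#' )
#' sheet
count_sheet <- function(data, control, experiment_name = "lifespan",
                        temperature_c = NULL, researchers = NULL,
                        colors = NULL) {
  required <- c("condition", "day", "alive", "died", "censored")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    ws_error(
      paste0("count sheet is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "wormspan_format_error"
    )
  }
  data <- tibble::as_tibble(data)[required]
  data$condition <- as.character(data$condition)
  for (col in c("day", "alive", "died", "censored")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  sheet <- structure(
    list(
      data = data,
      control = as.character(control),
      experiment_name = as.character(experiment_name),
      temperature_c = if (is.null(temperature_c)) NULL else as.numeric(temperature_c),
      researchers = if (is.null(researchers)) NULL else as.character(researchers),
      colors = colors
    ),
    class = "count_sheet"
  )
  validate_count_sheet(sheet)
}

#' Validate a count sheet
#'
#' Checks the bookkeeping invariants of a scoring sheet: non-negative counts,
#' strictly increasing observation days within each condition, the identity
#' `alive[k] = alive[k-1] - died[k] - censored[k]`, at least one worm per
#' condition, no deaths/censoring recorded at day 0 (event times must be
#' positive), and a control label present among the conditions.
#'
#' @param sheet A `count_sheet`.
#' @return The sheet, invisibly unchanged, if valid; otherwise an error of
#'   class `wormspan_validation_error` naming the offending condition and day.
#' @export
validate_count_sheet <- function(sheet) {
  stopifnot(inherits(sheet, "count_sheet"))
  data <- sheet$data
  if (nrow(data) == 0) {
    ws_error("count sheet contains no observation rows",
             "wormspan_format_error")
  }
  bad <- data[!stats::complete.cases(data[c("day", "alive", "died", "censored")]), ]
  if (nrow(bad) > 0) {
    ws_error("count sheet has non-numeric or missing values in day/alive/died/censored",
             "wormspan_format_error")
  }
  counts <- data[c("alive", "died", "censored")]
  if (any(unlist(counts) < 0) || any(data$day < 0)) {
    ws_error("count sheet has negative counts or days",
             "wormspan_validation_error")
  }
  for (cond in unique(data$condition)) {
    rows <- data[data$condition == cond, ]
    if (any(diff(rows$day) <= 0)) {
      ws_error(
        sprintf("condition '%s': observation days are not strictly increasing", cond),
        "wormspan_validation_error"
      )
    }
    n0 <- rows$alive[1] + rows$died[1] + rows$censored[1]
    if (n0 < 1) {
      ws_error(sprintf("condition '%s': initial number of worms is zero", cond),
               "wormspan_validation_error")
    }
    if (nrow(rows) > 1) {
      expected <- rows$alive[-nrow(rows)] - rows$died[-1] - rows$censored[-1]
      mismatch <- which(rows$alive[-1] != expected)
      if (length(mismatch) > 0) {
        k <- mismatch[1] + 1
        ws_error(
          sprintf(
            "condition '%s', day %g: alive = %g but previous alive - died - censored = %g",
            cond, rows$day[k], rows$alive[k], expected[mismatch[1]]
          ),
          "wormspan_validation_error"
        )
      }
    }
    day0_events <- rows$day == 0 & (rows$died > 0 | rows$censored > 0)
    if (any(day0_events)) {
      ws_error(
        sprintf("condition '%s': deaths/censoring recorded at day 0 (event times must be positive)", cond),
        "wormspan_validation_error"
      )
    }
  }
  if (!sheet$control %in% data$condition) {
    ws_error(
      sprintf("control condition '%s' does not appear in the sheet (conditions: %s)",
              sheet$control, paste(unique(data$condition), collapse = ", ")),
      "wormspan_validation_error"
    )
  }
  invisible(sheet)
}

#' @export
print.count_sheet <- function(x, ...) {
  cat("<count_sheet> ", x$experiment_name, "\n", sep = "")
  conds <- unique(x$data$condition)
  cat("  conditions: ", paste(conds, collapse = ", "),
      " (control: ", x$control, ")\n", sep = "")
  if (!is.null(x$temperature_c)) cat("  temperature: ", x$temperature_c, " degC\n", sep = "")
  if (!is.null(x$researchers)) cat("  researchers: ", paste(x$researchers, collapse = ", "), "\n", sep = "")
  print(x$data, ...)
  invisible(x)
}

# parse '#key: value' metadata lines from the top of a count-sheet CSV
parse_sheet_metadata <- function(lines) {
  meta_lines <- lines[startsWith(trimws(lines), "#")]
  meta <- list(control = NULL, temperature_c = NULL, researchers = NULL,
               colors = NULL, experiment_name = NULL)
  for (line in meta_lines) {
    body <- sub("^\\s*#", "", line)
    if (!grepl(":", body, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", body))
    value <- trimws(sub("^[^:]*:", "", body))
    if (key == "control") {
      meta$control <- value
    } else if (key == "experiment") {
      meta$experiment_name <- value
    } else if (key == "temperature_c") {
      meta$temperature_c <- as.numeric(value)
    } else if (key == "researchers") {
      meta$researchers <- trimws(strsplit(value, ",")[[1]])
    } else if (startsWith(key, "color")) {
      # '#color:<condition>=<color>' ; value is '<condition>=<color>'
      cond <- trimws(sub("=.*$", "", value))
      col <- trimws(sub("^[^=]*=", "", value))
      meta$colors <- c(meta$colors, setNames(col, cond))
    }
  }
  meta
}

#' Read a lifespan scoring sheet
#'
#' Reads a count sheet from disk. The canonical dialect is a long-format CSV
#' with header `condition,day,alive,died,censored`, optionally preceded by
#' metadata comment lines:
#' ```
#' #control: N2
#' #temperature_c: 20
#' #researchers: BLM, JP
#' #color:daf-2 RNAi=#D55E00
#' condition,day,alive,died,censored
#' N2,0,10,0,0
#' ...
#' ```
#' Excel workbooks are read from the first sheet, mapping columns A-E to the
#' same five fields; rows whose first cell starts with `#` are treated as the
#' same metadata lines. A blank template ships with the package:
#' `system.file("extdata", "lifespan_template.csv", package = "wormspan")`.
#'
#' @param path Path to the file.
#' @param dialect One of `"csv"`, `"xlsx"`, `"ods"`; defaults to the file
#'   extension. Reading ODS requires the readODS package.
#' @param control Override the control label from the file metadata.
#' @param experiment_name Experiment name; defaults to the `#experiment:`
#'   metadata line or the file name.
#' @return A validated [count_sheet()].
#' @export
read_count_sheet <- function(path, dialect = c("auto", "csv", "xlsx", "ods"),
                             control = NULL, experiment_name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    ws_error(sprintf("count sheet file not found: %s", path), "wormspan_io_error")
  }
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("xlsx", "ods")) ext else "csv"
  }
  if (dialect == "csv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (length(lines) == 0 || all(trimws(lines) == "")) {
      ws_error(sprintf("count sheet file is empty: %s", path), "wormspan_format_error")
    }
    meta <- parse_sheet_metadata(lines)
    data <- suppressWarnings(readr::read_csv(
      I(paste(lines, collapse = "\n")),
      comment = "#", show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        condition = readr::col_character(),
        .default = readr::col_double()
      )
    ))
  } else if (dialect == "xlsx") {
    raw <- readxl::read_excel(path, col_names = FALSE, col_types = "text",
                              .name_repair = "minimal")
    if (nrow(raw) == 0) {
      ws_error(sprintf("count sheet file is empty: %s", path), "wormspan_format_error")
    }
    names(raw) <- paste0("c", seq_len(ncol(raw)))
    first <- as.character(raw[[1]])
    meta_rows <- !is.na(first) & startsWith(trimws(first), "#")
    meta <- parse_sheet_metadata(first[meta_rows])
    body <- raw[!meta_rows, , drop = FALSE]
    header_row <- which(!is.na(body[[1]]) & trimws(tolower(body[[1]])) == "condition")
    if (length(header_row) == 0) {
      ws_error("xlsx count sheet has no 'condition' header row", "wormspan_format_error")
    }
    hdr <- as.character(unlist(body[header_row[1], ]))
    body <- body[-seq_len(header_row[1]), , drop = FALSE]
    body <- body[!is.na(body[[1]]) & trimws(body[[1]]) != "", , drop = FALSE]
    names(body) <- trimws(tolower(hdr))
    data <- tibble::tibble(
      condition = as.character(body[["condition"]]),
      day = as.numeric(body[["day"]]),
      alive = as.numeric(body[["alive"]]),
      died = as.numeric(body[["died"]]),
      censored = as.numeric(body[["censored"]])
    )
  } else {
    if (!requireNamespace("readODS", quietly = TRUE)) {
      ws_error("reading .ods count sheets requires the readODS package; export the sheet as CSV or xlsx instead",
               "wormspan_io_error")
    }
    raw <- readODS::read_ods(path, col_names = TRUE)
    meta <- list(control = NULL, temperature_c = NULL, researchers = NULL,
                 colors = NULL, experiment_name = NULL)
    data <- tibble::as_tibble(raw)
  }
  required <- c("condition", "day", "alive", "died", "censored")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    ws_error(
      paste0("count sheet is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "wormspan_format_error"
    )
  }
  control <- control %||% meta$control
  if (is.null(control)) {
    ws_error("no control condition designated (add a '#control: <label>' line or pass `control`)",
             "wormspan_validation_error")
  }
  name <- experiment_name %||% meta$experiment_name %||%
    tools::file_path_sans_ext(basename(path))
  count_sheet(data,
              control = control,
              experiment_name = name,
              temperature_c = meta$temperature_c,
              researchers = meta$researchers,
              colors = meta$colors)
}

#' Write a count sheet to the canonical CSV dialect
#'
#' @param sheet A [count_sheet()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_sheet <- function(sheet, path) {
  validate_count_sheet(sheet)
  meta <- c(
    paste0("#experiment: ", sheet$experiment_name),
    paste0("#control: ", sheet$control),
    if (!is.null(sheet$temperature_c)) paste0("#temperature_c: ", sheet$temperature_c),
    if (!is.null(sheet$researchers)) paste0("#researchers: ", paste(sheet$researchers, collapse = ", ")),
    if (!is.null(sheet$colors)) paste0("#color:", names(sheet$colors), "=", unname(sheet$colors))
  )
  body <- readr::format_csv(sheet$data)
  writeLines(c(meta, sub("\n$", "", body)), path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
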