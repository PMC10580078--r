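#' Analyze an event table: estimation, testing, annotation
#'
#' The estimation stage shared by [autoplot_lifespan()] and
#' [manualplot_lifespan()]: fits a Kaplan-Meier curve per condition,
#' summarizes lifespans, runs [gehan_test()] of every non-control condition
#' against the control, and assembles the legend.
#'
#' @param table An [event_table()] with a designated control.
#' @return A list with `curves` (named list of `km_curve`), `reports`
#'   (tibble: condition, n, n_deaths, n_censored, mean_lifespan,
#'   median_lifespan, statistic, p_value, stars; control row first) and
#'   `legend` (from [build_legend()]).
#' @export
analyze_experiment <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (is.na(table$control) || !table$control %in% table$events$condition) {
    ws_error(sprintf("no control condition designated (got '%s')", table$control),
             "wormspan_validation_error")
  }
  conds <- condition_order(table)
  curves <- km_curves(table)
  control_rec <- dplyr::filter(table$events, .data$condition == table$control)
  reports <- purrr::map_dfr(conds, function(cond) {
    rec <- dplyr::filter(table$events, .data$condition == cond)
    row <- summarize_condition(rec, condition = cond)
    if (cond == table$control) {
      row$statistic <- NA_real_
      row$p_value <- NA_real_
    } else {
      test <- gehan_test(control_rec, rec)
      row$statistic <- unname(test$statistic)
      row$p_value <- test$p.value
    }
    row
  })
  legend <- build_legend(reports, table$control)
  reports$stars <- legend$stars[match(reports$condition, legend$condition)]
  list(curves = curves, reports = reports, legend = legend)
}

# timestamped info line on stderr
ws_log <- function(..., quiet = FALSE) {
  if (!quiet) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
}

# files in a directory that look like count sheets (skips our own outputs)
find_count_sheets <- function(directory) {
  files <- list.files(directory, pattern = "\\.(csv|xlsx|ods)$",
                      full.names = TRUE, ignore.case = TRUE)
  skip <- grepl("(_km|_summary|_events)\\.csv$", files, ignore.case = TRUE)
  sort(files[!skip])
}

# pool several sheets into one experiment: each sheet is flattened on its
# own (per-sheet bookkeeping stays intact), then events are concatenated
combine_sheets <- function(sheets, experiment_name) {
  controls <- unique(vapply(sheets, function(s) s$control, character(1)))
  if (length(controls) > 1) {
    ws_error(sprintf("sheets disagree on the control condition: %s",
                     paste(controls, collapse = " vs ")),
             "wormspan_validation_error")
  }
  tables <- lapply(sheets, convert_counts)
  events <- dplyr::bind_rows(lapply(tables, function(tb) tb$events))
  temps <- unlist(lapply(sheets, function(s) s$temperature_c))
  res <- unique(unlist(lapply(sheets, function(s) s$researchers)))
  colors <- NULL
  for (s in sheets) colors <- c(colors, s$colors)
  if (!is.null(colors)) colors <- colors[!duplicated(names(colors))]
  event_table(events,
              control = controls,
              experiment_name = experiment_name,
              temperature_c = if (length(temps) > 0) temps[1] else NULL,
              researchers = if (length(res) > 0) res else NULL,
              colors = colors)
}

#' Analyze and plot one lifespan experiment directory
#'
#' The one-call workflow: reads every scoring sheet in `directory` (multiple
#' sheets are pooled into one experiment and must agree on the control),
#' flattens counts to events, fits Kaplan-Meier curves, tests every condition
#' against the control, and writes an annotated SVG survival plot titled with
#' the directory's base name. Conditions whose lifespan differs significantly
#' from the control (p < `alpha`) additionally get an individual
#' control-vs-condition SVG, drawn in the same color as in the main plot.
#'
#' @param directory Directory containing one experiment's count sheets.
#' @param out_dir Where outputs are written; defaults to `directory`.
#' @param write_data Also write the plotted KM step data
#'   (`<title>_km.csv`), the per-condition summary (`<title>_summary.csv`:
#'   condition, n, mean_lifespan, median_lifespan, statistic, p_value,
#'   stars) and the flattened events (`<title>_events.csv`).
#' @param return_data Return the analysis without writing any files.
#' @param alpha Significance threshold for individual comparison plots.
#' @param colors Named color overrides (take precedence over in-sheet
#'   `#color:` lines).
#' @param x_limits Numeric length-2 x-axis limits in days, or `NULL` (auto).
#' @param quiet Suppress informational log lines on stderr.
#' @return An object of class `experiment_result`: a list with `title`,
#'   `reports`, `curves`, `legend`, `caption`, `km_data`, `summary`,
#'   `svg_main` and `svg_individual` (in-memory documents), and -- unless
#'   `return_data` -- `main_plot_path`, `individual_plot_paths`,
#'   `data_out_paths`.
#' @export
autoplot_lifespan <- function(directory, out_dir = directory,
                              write_data = FALSE, return_data = FALSE,
                              alpha = 0.05, colors = NULL, x_limits = NULL,
                              quiet = FALSE) {
  if (!dir.exists(directory)) {
    ws_error(sprintf("directory not found: %s", directory), "wormspan_io_error")
  }
  files <- find_count_sheets(directory)
  if (length(files) == 0) {
    ws_error(sprintf("no count sheets (*.csv, *.xlsx) found in %s", directory),
             "wormspan_io_error")
  }
  title <- basename(normalizePath(directory))
  sheets <- lapply(files, read_count_sheet)
  table <- combine_sheets(sheets, experiment_name = title)
  if (!is.null(colors)) {
    table$colors <- c(colors, table$colors)[!duplicated(c(names(colors), names(table$colors)))]
  }
  ws_log("analyzing '", title, "': ", length(files), " sheet(s), ",
         length(unique(table$events$condition)), " condition(s)", quiet = quiet)
  result <- build_experiment_result(table, title = title, alpha = alpha,
                                    x_limits = x_limits)
  if (!return_data) {
    result <- write_experiment_result(result, out_dir, write_data = write_data,
                                      quiet = quiet)
  }
  result
}

#' Plot a prepared event table with manual presentation control
#'
#' The manual entry point: takes an already flattened [event_table()] (e.g.
#' from [convert_counts()] or [read_event_table()]) and runs the pipeline
#' from the estimation stage onward, honoring a user-supplied title, x-axis
#' limits and colors over the automatic defaults.
#'
#' @param table An [event_table()] with a designated control.
#' @param title Plot title; defaults to the table's experiment name.
#' @param x_limits Numeric length-2 x limits in days; an error is raised if
#'   they exclude every recorded event.
#' @param colors Named color overrides.
#' @param alpha Significance threshold for individual comparison plots.
#' @param out_dir Output directory; `NULL` (default) returns the documents
#'   without writing files.
#' @param write_data As in [autoplot_lifespan()].
#' @param quiet Suppress log lines.
#' @return An `experiment_result` (see [autoplot_lifespan()]).
#' @export
manualplot_lifespan <- function(table, title = NULL, x_limits = NULL,
                                colors = NULL, alpha = 0.05, out_dir = NULL,
                                write_data = FALSE, quiet = FALSE) {
  stopifnot(inherits(table, "event_table"))
  if (!is.null(x_limits)) {
    stopifnot(is.numeric(x_limits), length(x_limits) == 2)
    inside <- table$events$time >= x_limits[1] & table$events$time <= x_limits[2]
    if (nrow(table$events) > 0 && !any(inside)) {
      ws_error("x_limits exclude every recorded event", "wormspan_argument_error")
    }
  }
  if (!is.null(colors)) {
    table$colors <- c(colors, table$colors)[!duplicated(c(names(colors), names(table$colors)))]
  }
  result <- build_experiment_result(
    table,
    title = title %||% table$experiment_name,
    alpha = alpha, x_limits = x_limits
  )
  if (!is.null(out_dir)) {
    result <- write_experiment_result(result, out_dir, write_data = write_data,
                                      quiet = quiet)
  }
  result
}

# shared core: analyze + render, no file I/O
build_experiment_result <- function(table, title, alpha = 0.05,
                                    x_limits = NULL) {
  analysis <- analyze_experiment(table)
  spec <- plot_spec(
    title = title,
    x_min = if (!is.null(x_limits)) x_limits[1] else NULL,
    x_max = if (!is.null(x_limits)) x_limits[2] else NULL,
    colors = resolve_colors(analysis$legend$condition, table$colors),
    temperature_c = table$temperature_c,
    researchers = table$researchers
  )
  svg_main <- render_survival_plot(analysis$curves, analysis$legend, spec)
  sig <- analysis$reports$condition[
    !is.na(analysis$reports$p_value) & analysis$reports$p_value < alpha
  ]
  control <- table$control
  svg_individual <- lapply(sig, function(cond) {
    render_single_comparison(
      analysis$curves[[control]], analysis$curves[[cond]],
      analysis$legend, spec,
      all_conditions = analysis$legend$condition
    )
  })
  names(svg_individual) <- sig
  summary_tbl <- dplyr::select(
    analysis$reports,
    "condition", "n", "mean_lifespan", "median_lifespan",
    "statistic", "p_value", "stars"
  )
  structure(
    list(
      title = title,
      control = control,
      alpha = alpha,
      table = table,
      curves = analysis$curves,
      reports = analysis$reports,
      legend = analysis$legend,
      caption = build_caption(table$temperature_c, table$researchers),
      km_data = km_table(analysis$curves),
      summary = summary_tbl,
      svg_main = svg_main,
      svg_individual = svg_individual,
      main_plot_path = NULL,
      individual_plot_paths = list(),
      data_out_paths = character()
    ),
    class = "experiment_result"
  )
}

# write the SVGs (and optionally the data) of a built result
write_experiment_result <- function(result, out_dir, write_data = FALSE,
                                    quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  safe <- svg_id_fragment(result$title)
  main_path <- file.path(out_dir, paste0(safe, ".svg"))
  write_svg(result$svg_main, main_path)
  result$main_plot_path <- main_path
  result$individual_plot_paths <- list()
  for (cond in names(result$svg_individual)) {
    p <- file.path(out_dir, paste0(safe, "__", svg_id_fragment(cond), ".svg"))
    write_svg(result$svg_individual[[cond]], p)
    result$individual_plot_paths[[cond]] <- p
  }
  if (write_data) {
    km_path <- file.path(out_dir, paste0(safe, "_km.csv"))
    sum_path <- file.path(out_dir, paste0(safe, "_summary.csv"))
    ev_path <- file.path(out_dir, paste0(safe, "_events.csv"))
    readr::write_csv(result$km_data, km_path, progress = FALSE)
    readr::write_csv(result$summary, sum_path, progress = FALSE)
    write_event_table(result$table, ev_path)
    result$data_out_paths <- c(km = km_path, summary = sum_path, events = ev_path)
  }
  ws_log("wrote ", basename(main_path),
         if (length(result$individual_plot_paths) > 0) {
           paste0(" + ", length(result$individual_plot_paths), " individual plot(s)")
         } else "",
         quiet = quiet)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$title, "\n", sep = "")
  cat("  control: ", x$control, "\n", sep = "")
  print(x$summary)
  if (!is.null(x$main_plot_path)) cat("  main plot: ", x$main_plot_path, "\n", sep = "")
  if (length(x$individual_plot_paths) > 0) {
    cat("  individual plots: ",
        paste(basename(unlist(x$individual_plot_paths)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Batch-process a parent directory of experiments
#'
#' Applies [autoplot_lifespan()] to every daughter directory of
#' `parent_directory` that contains at least one count sheet. A failure in
#' one daughter is caught and logged; the remaining daughters are still
#' processed, and the returned list always has one element per attempted
#' daughter (an `experiment_result` or a `wormspan_failure` record).
#'
#' @param parent_directory Directory whose subdirectories each hold one
#'   experiment.
#' @param ... Passed on to [autoplot_lifespan()].
#' @param quiet Suppress log lines.
#' @return A named list (one entry per daughter) of `experiment_result` or
#'   `wormspan_failure` objects, with attribute `n_failed`.
#' @export
batch_autoplot <- function(parent_directory, ..., quiet = FALSE) {
  if (!dir.exists(parent_directory)) {
    ws_error(sprintf("directory not found: %s", parent_directory),
             "wormspan_io_error")
  }
  daughters <- list.dirs(parent_directory, recursive = FALSE)
  daughters <- daughters[vapply(daughters,
                                function(d) length(find_count_sheets(d)) > 0,
                                logical(1))]
  if (length(daughters) == 0) {
    ws_error(sprintf("no daughter directories with count sheets under %s",
                     parent_directory),
             "wormspan_io_error")
  }
  results <- lapply(daughters, function(d) {
    tryCatch(
      autoplot_lifespan(d, ..., quiet = quiet),
      error = function(e) {
        # failures are error-level: logged even under quiet
        ws_log("FAILED '", basename(d), "': ", conditionMessage(e),
               quiet = FALSE)
        structure(list(directory = d, error = conditionMessage(e)),
                  class = "wormspan_failure")
      }
    )
  })
  names(results) <- basename(daughters)
  n_failed <- sum(vapply(results, inherits, logical(1), "wormspan_failure"))
  ws_log("batch complete: ", length(results) - n_failed, " succeeded, ",
         n_failed, " failed", quiet = quiet)
  attr(results, "n_failed") <- n_failed
  results
}
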