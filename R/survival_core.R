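#' Kaplan-Meier survival estimate for one condition
#'
#' Computes the product-limit estimate of the survival function from
#' right-censored event records. At each distinct death time `t_k` with
#' `d_k` deaths among `r_k` worms at risk, the curve drops by the factor
#' `(1 - d_k/r_k)`; worms censored at `t_k` are still at risk for deaths at
#' `t_k` (the standard deaths-before-censoring tie convention). The curve
#' starts at S = 1 at time 0. The fit itself is delegated to
#' [survival::survfit()].
#'
#' @param records A data frame with columns `time` and `status`
#'   (`"DEATH"`/`"CENSORED"`), or an [event_table()] containing a single
#'   condition. All records must belong to one condition.
#' @param condition Condition label to attach to the curve; inferred from a
#'   `condition` column when present.
#' @return An object of class `km_curve`: a tibble with one row per distinct
#'   death time and columns `time`, `n_risk`, `n_event`, `survival`, plus
#'   attributes `condition`, `n_total`, `n_deaths`, `n_censored` and
#'   `max_time` (latest observed time, death or censoring).
#' @export
#' @examples
#' rec <- data.frame(time = c(2, 3, 5, 5),
#'                   status = c("DEATH", "CENSORED", "DEATH", "DEATH"))
#' km_estimate(rec, condition = "N2")
km_estimate <- function(records, condition = NULL) {
  records <- as_event_records(records)
  if (nrow(records) == 0) {
    ws_error("km_estimate() needs at least one event record",
             "wormspan_argument_error")
  }
  if ("condition" %in% names(records)) {
    conds <- unique(records$condition)
    if (length(conds) > 1) {
      ws_error("km_estimate() expects records from a single condition; got several",
               "wormspan_argument_error")
    }
    condition <- condition %||% conds
  }
  condition <- condition %||% "condition"
  is_death <- records$status == "DEATH"
  fit <- survival::survfit(
    survival::Surv(records$time, is_death) ~ 1,
    conf.type = "none"
  )
  keep <- fit$n.event > 0
  curve <- tibble::tibble(
    time = fit$time[keep],
    n_risk = as.integer(fit$n.risk[keep]),
    n_event = as.integer(fit$n.event[keep]),
    survival = fit$surv[keep]
  )
  structure(
    curve,
    class = c("km_curve", class(curve)),
    condition = condition,
    n_total = nrow(records),
    n_deaths = sum(is_death),
    n_censored = sum(!is_death),
    max_time = max(records$time)
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> ", attr(x, "condition"),
      ": n = ", attr(x, "n_total"),
      ", deaths = ", attr(x, "n_deaths"),
      ", censored = ", attr(x, "n_censored"), "\n", sep = "")
  NextMethod()
}

#' Mean lifespan of a condition
#'
#' The arithmetic mean of observed death times; censored animals are
#' excluded, as is conventional in worm lifespan reporting (this is not the
#' restricted mean survival time).
#'
#' @inheritParams km_estimate
#' @return Mean death day, or `NA_real_` when the condition has no deaths
#'   (legends then show n only).
#' @export
mean_lifespan <- function(records) {
  records <- as_event_records(records)
  deaths <- records$time[records$status == "DEATH"]
  if (length(deaths) == 0) return(NA_real_)
  mean(deaths)
}

#' Median lifespan from a Kaplan-Meier curve
#'
#' The smallest death time at which the estimated survival is at or below
#' 0.5; `NA` when the curve never reaches 0.5 (more than half the worms
#' censored or alive at the end of scoring).
#'
#' @param curve A [km_estimate()] result.
#' @return Median day or `NA_real_`.
#' @export
median_lifespan <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$survival <= 0.5)
  if (length(hit) == 0) return(NA_real_)
  curve$time[hit[1]]
}

#' Lifespan summary for one condition
#'
#' @inheritParams km_estimate
#' @return A one-row tibble: `condition`, `n`, `n_deaths`, `n_censored`,
#'   `mean_lifespan`, `median_lifespan`.
#' @export
summarize_condition <- function(records, condition = NULL) {
  records <- as_event_records(records)
  curve <- km_estimate(records, condition = condition)
  tibble::tibble(
    condition = attr(curve, "condition"),
    n = attr(curve, "n_total"),
    n_deaths = attr(curve, "n_deaths"),
    n_censored = attr(curve, "n_censored"),
    mean_lifespan = mean_lifespan(records),
    median_lifespan = median_lifespan(curve)
  )
}

#' Kaplan-Meier curves for every condition in an event table
#'
#' @param table An [event_table()].
#' @return Named list of [km_estimate()] curves, control first, then the
#'   other conditions in order of first appearance.
#' @export
km_curves <- function(table) {
  stopifnot(inherits(table, "event_table"))
  conds <- condition_order(table)
  curves <- lapply(conds, function(cond) {
    km_estimate(dplyr::filter(table$events, .data$condition == cond))
  })
  setNames(curves, conds)
}

#' Combined KM step data as a tibble
#'
#' Long-format export of one or more curves, suitable for writing out the
#' plotted data (`condition,time,survival,n_at_risk,n_events`).
#'
#' @param curves A `km_curve` or a list of them.
#' @return A tibble with columns `condition`, `time`, `survival`,
#'   `n_at_risk`, `n_events`.
#' @export
km_table <- function(curves) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  purrr::map_dfr(curves, function(cv) {
    tibble::tibble(
      condition = attr(cv, "condition"),
      time = cv$time,
      survival = cv$survival,
      n_at_risk = cv$n_risk,
      n_events = cv$n_event
    )
  })
}

#' @rdname km_estimate
#' @param object,x A `km_curve`.
#' @param ... Unused.
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) km_table(x)

# coerce event_table / data frame input to a plain records tibble
as_event_records <- function(records) {
  if (inherits(records, "event_table")) return(records$events)
  if (!is.data.frame(records)) {
    ws_error("expected an event_table or a data frame of event records",
             "wormspan_argument_error")
  }
  missing_cols <- setdiff(c("time", "status"), names(records))
  if (length(missing_cols) > 0) {
    ws_error(paste0("event records are missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "wormspan_format_error")
  }
  tibble::as_tibble(records)
}

# control first, then others by first appearance
condition_order <- function(table) {
  conds <- unique(table$events$condition)
  c(table$control, setdiff(conds, table$control))
}
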