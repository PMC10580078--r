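#' Specify one simulated assay arm
#'
#' @param label Condition label (e.g. `"N2"`, `"daf-2 RNAi"`).
#' @param dist Lifetime distribution: `"exponential"` or `"weibull"`.
#' @param rate Exponential rate (deaths per day); mean lifespan is `1/rate`.
#' @param shape,scale Weibull shape and scale (days). Worm lifespan cohorts
#'   are typically Weibull-like with shape around 3-5.
#' @param n Number of worms in the arm.
#' @param censor_prob Per-observation probability that a surviving worm is
#'   censored that day (a simple surrogate for missing/bagged/exploded
#'   animals), in `[0, 1)`.
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(label, dist = c("weibull", "exponential"),
                           rate = NULL, shape = NULL, scale = NULL,
                           n = 50, censor_prob = 0) {
  dist <- match.arg(dist)
  if (dist == "exponential") {
    stopifnot(!is.null(rate), rate > 0)
  } else {
    stopifnot(!is.null(shape), !is.null(scale), shape > 0, scale > 0)
  }
  stopifnot(n >= 1, censor_prob >= 0, censor_prob < 1)
  structure(
    list(label = label, dist = dist, rate = rate, shape = shape,
         scale = scale, n = n, censor_prob = censor_prob),
    class = "condition_spec"
  )
}

#' Specify a synthetic lifespan experiment
#'
#' @param conditions List of [condition_spec()]s; the first is the control
#'   unless `control` says otherwise.
#' @param observation_interval Days between scoring sessions (1 = daily).
#' @param max_day Last scoring day; survivors are censored there.
#' @param seed Integer seed; identical seeds give identical sheets.
#' @param control Label of the control condition.
#' @param experiment_name,temperature_c,researchers Sheet metadata.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(conditions, observation_interval = 1, max_day = 60,
                     seed = 1L, control = conditions[[1]]$label,
                     experiment_name = "simulated lifespan",
                     temperature_c = 20, researchers = NULL) {
  stopifnot(length(conditions) >= 1, observation_interval > 0, max_day > 0)
  labels <- vapply(conditions, function(cs) cs$label, character(1))
  stopifnot(control %in% labels, !anyDuplicated(labels))
  structure(
    list(conditions = conditions,
         observation_interval = observation_interval,
         max_day = max_day, seed = as.integer(seed), control = control,
         experiment_name = experiment_name, temperature_c = temperature_c,
         researchers = researchers),
    class = "sim_spec"
  )
}

# draw true lifetimes for one arm
draw_lifetimes <- function(cs) {
  if (cs$dist == "exponential") rexp(cs$n, rate = cs$rate)
  else rweibull(cs$n, shape = cs$shape, scale = cs$scale)
}

#' Simulate a scored lifespan experiment
#'
#' Draws a true death day per worm from its arm's lifetime distribution, then
#' emulates manual scoring: observations happen every
#' `observation_interval` days, a death is recorded at the first observation
#' at or after the true death time, each still-living worm is independently
#' censored at each observation with probability `censor_prob`, and worms
#' alive at `max_day` are censored there. The result is a valid
#' [count_sheet()] satisfying the bookkeeping identity; identical seeds give
#' identical sheets.
#'
#' @param spec A [sim_spec()].
#' @return A validated [count_sheet()].
#' @export
#' @examples
#' spec <- sim_spec(
#'   list(condition_spec("N2", "weibull", shape = 4, scale = 17, n = 30),
#'        condition_spec("daf-2 RNAi", "weibull", shape = 4, scale = 26, n = 30)),
#'   max_day = 50, seed = 42
#' )
#' simulate_experiment(spec)
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  obs_days <- seq(spec$observation_interval, spec$max_day,
                  by = spec$observation_interval)
  if (tail(obs_days, 1) < spec$max_day) obs_days <- c(obs_days, spec$max_day)
  rows <- withr::with_seed(spec$seed, {
    purrr::map_dfr(spec$conditions, function(cs) {
      true_death <- draw_lifetimes(cs)
      alive <- rep(TRUE, cs$n)
      out <- tibble::tibble(condition = cs$label, day = 0,
                            alive = cs$n, died = 0, censored = 0)
      n_alive <- cs$n
      for (d in obs_days) {
        if (n_alive == 0) break
        dies <- alive & true_death <= d
        n_died <- sum(dies)
        alive[dies] <- FALSE
        surv_idx <- which(alive)
        if (d >= spec$max_day) {
          n_cens <- length(surv_idx)
          alive[surv_idx] <- FALSE
        } else if (cs$censor_prob > 0 && length(surv_idx) > 0) {
          cens <- surv_idx[rbinom(length(surv_idx), 1, cs$censor_prob) == 1]
          n_cens <- length(cens)
          alive[cens] <- FALSE
        } else {
          n_cens <- 0L
        }
        n_alive <- n_alive - n_died - n_cens
        out <- dplyr::bind_rows(out, tibble::tibble(
          condition = cs$label, day = d,
          alive = n_alive, died = n_died, censored = n_cens
        ))
      }
      out
    })
  })
  count_sheet(rows,
              control = spec$control,
              experiment_name = spec$experiment_name,
              temperature_c = spec$temperature_c,
              researchers = spec$researchers)
}

#' Write a suite of example experiment directories
#'
#' Creates three daughter directories -- `rnai/`, `genotype/` and `drug/` --
#' each containing one synthetic count sheet with a control and a treatment
#' whose true lifespan is shifted, mirroring the common RNAi, mutant and drug
#' assay layouts. The tree is directly usable as [batch_autoplot()] input.
#'
#' @param out_dir Directory to create the suite under.
#' @param seed Integer seed.
#' @param n Worms per arm.
#' @return `out_dir`, invisibly; side effect: three sheets on disk.
#' @export
make_example_suite <- function(out_dir, seed = 1L, n = 60) {
  specs <- list(
    rnai = sim_spec(
      list(
        condition_spec("EV", "weibull", shape = 4, scale = 17, n = n,
                       censor_prob = 0.01),
        condition_spec("daf-2 RNAi", "weibull", shape = 4, scale = 26, n = n,
                       censor_prob = 0.01)
      ),
      max_day = 60, seed = seed, control = "EV",
      experiment_name = "rnai lifespan", researchers = c("AA", "BB")
    ),
    genotype = sim_spec(
      list(
        condition_spec("N2", "weibull", shape = 4, scale = 17, n = n,
                       censor_prob = 0.01),
        condition_spec("daf-16(mu86)", "weibull", shape = 4, scale = 12, n = n,
                       censor_prob = 0.01)
      ),
      max_day = 60, seed = seed + 1L, control = "N2",
      experiment_name = "genotype lifespan", researchers = c("AA")
    ),
    drug = sim_spec(
      list(
        condition_spec("vehicle", "weibull", shape = 4, scale = 17, n = n,
                       censor_prob = 0.01),
        condition_spec("rapamycin 100 uM", "weibull", shape = 4, scale = 22,
                       n = n, censor_prob = 0.01)
      ),
      max_day = 60, seed = seed + 2L, control = "vehicle",
      experiment_name = "drug lifespan", researchers = c("CC")
    )
  )
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    ws_error(sprintf("cannot create directory '%s'", out_dir),
             "wormspan_io_error")
  }
  for (name in names(specs)) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    write_count_sheet(simulate_experiment(specs[[name]]),
                      file.path(d, paste0(name, "_sheet.csv")))
  }
  invisible(out_dir)
}
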