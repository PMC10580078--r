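test_that("product-limit estimate matches the hand-computed 4-worm example", {
  rec <- data.frame(time = c(2, 3, 5, 5),
                    status = c("DEATH", "CENSORED", "DEATH", "DEATH"))
  cv <- km_estimate(rec, condition = "N2")
  expect_equal(cv$time, c(2, 5))
  expect_equal(cv$n_risk, c(4L, 2L))
  expect_equal(cv$n_event, c(1L, 2L))
  expect_equal(cv$survival, c(0.75, 0))
  expect_equal(attr(cv, "n_total"), 4)
  expect_equal(attr(cv, "n_censored"), 1)
})

test_that("with no censoring the curve equals the empirical survival function", {
  for (seed in 1:10) {
    times <- withr::with_seed(seed, sample(1:30, 25, replace = TRUE))
    cv <- km_estimate(death_records(times))
    for (k in seq_len(nrow(cv))) {
      expect_equal(cv$survival[k], empirical_survival(times, cv$time[k]))
    }
  }
  # one death per day, n = 10: survival after k-th death is (10 - k)/10
  cv <- km_estimate(death_records(1:10))
  expect_equal(cv$survival, (10 - 1:10) / 10)
})

test_that("late censoring adds no event times; survival counts it as surviving", {
  rec <- death_records(c(3, 5, 5, 9, 12))
  base <- km_estimate(rec)
  extended <- km_estimate(rbind(rec, data.frame(time = 20, status = "CENSORED")))
  # a censored record is never an event time
  expect_equal(extended$time, base$time)
  # with all censoring after the last death, the product-limit estimate
  # reduces to simple counting over all n+1 worms (censored one survives)
  n <- 6
  for (k in seq_len(nrow(extended))) {
    expect_equal(extended$survival[k],
                 sum(c(rec$time, 20) > extended$time[k]) / n)
  }
})

test_that("mean lifespan averages death days only", {
  expect_equal(mean_lifespan(death_records(c(2, 4))), 3)
  mixed <- rbind(death_records(c(7, 7, 7)),
                 data.frame(time = c(3, 20), status = "CENSORED"))
  expect_equal(mean_lifespan(mixed), 7)
  expect_equal(mean_lifespan(death_records(12.5)), 12.5)
  expect_true(is.na(mean_lifespan(data.frame(time = c(4, 8), status = "CENSORED"))))
})

test_that("median is the first time survival is at or below one half", {
  cv <- km_estimate(data.frame(time = c(2, 3, 5, 5),
                               status = c("DEATH", "CENSORED", "DEATH", "DEATH")))
  expect_equal(median_lifespan(cv), 5)
  # survival hits exactly 0.5: counts as crossed (inclusive rule)
  cv2 <- km_estimate(death_records(c(1, 1, 3, 3)))
  expect_equal(cv2$survival, c(0.5, 0))
  expect_equal(median_lifespan(cv2), 1)
  # never reaches 0.5
  cv3 <- km_estimate(rbind(death_records(2),
                           data.frame(time = rep(9, 9), status = "CENSORED")))
  expect_true(is.na(median_lifespan(cv3)))
})

test_that("summaries aggregate counts, mean and median consistently", {
  rec <- data.frame(time = c(2, 3, 5, 5),
                    status = c("DEATH", "CENSORED", "DEATH", "DEATH"))
  s <- summarize_condition(rec, condition = "N2")
  expect_equal(s$n, 4)
  expect_equal(s$n_deaths, 3)
  expect_equal(s$n_censored, 1)
  expect_equal(s$mean_lifespan, 4)
  expect_equal(s$median_lifespan, 5)
  expect_equal(s$n_deaths + s$n_censored, s$n)

  one <- summarize_condition(death_records(10))
  expect_equal(one$mean_lifespan, 10)
  expect_equal(one$median_lifespan, 10)
})

test_that("empty input is an argument error", {
  expect_error(km_estimate(data.frame(time = numeric(), status = character())),
               class = "wormspan_argument_error")
})

test_that("exponential parameters are recovered from uncensored lifespans", {
  # raw (unbinned) draws: mean near 1/rate, KM median near ln(2)/rate
  times <- withr::with_seed(421, rexp(5000, rate = 0.1))
  rec <- death_records(times)
  expect_lt(abs(mean_lifespan(rec) - 10) / 10, 0.05)
  cv <- km_estimate(rec)
  expect_lt(abs(median_lifespan(cv) - log(2) / 0.1) / (log(2) / 0.1), 0.05)

  # daily scoring records a death at the next observation, so binned times
  # follow ceil(T); the binned mean must match that distribution's mean
  sheet <- simulate_experiment(sim_spec(
    list(condition_spec("exp", "exponential", rate = 0.1, n = 5000)),
    observation_interval = 1, max_day = 200, seed = 421
  ))
  m <- mean_lifespan(convert_counts(sheet)$events)
  binned_truth <- 1 / (1 - exp(-0.1))  # E[ceil(T)], T ~ exp(0.1)
  expect_lt(abs(m - binned_truth) / binned_truth, 0.05)
})

test_that("km helpers expose tidy step data per condition", {
  table <- convert_counts(demo_sheet())
  curves <- km_curves(table)
  expect_named(curves, c("N2", "daf-2 RNAi"))  # control first
  tab <- km_table(curves)
  expect_named(tab, c("condition", "time", "survival", "n_at_risk", "n_events"))
  expect_identical(tidy(curves[["N2"]]), km_table(curves[["N2"]]))
  # survival non-increasing within each condition
  tab |>
    dplyr::group_by(condition) |>
    dplyr::summarize(ok = all(diff(survival) <= 0), .groups = "drop") |>
    dplyr::pull(ok) |>
    all() |>
    expect_true()
})
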