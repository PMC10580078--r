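# experiment directory with a clear lifespan shift (deterministic fixture)
make_experiment_dir <- function(root, name = "daf-2_vs_N2", seed = 11, n = 40) {
  d <- file.path(root, name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  sheet <- simulate_experiment(sim_spec(
    list(
      condition_spec("N2", "weibull", shape = 4, scale = 15, n = n,
                     censor_prob = 0.02),
      condition_spec("daf-2 RNAi", "weibull", shape = 4, scale = 25, n = n,
                     censor_prob = 0.02)
    ),
    max_day = 55, seed = seed, control = "N2",
    temperature_c = 20, researchers = c("AB")
  ))
  write_count_sheet(sheet, file.path(d, "sheet.csv"))
  d
}

test_that("autoplot titles from the directory and writes the expected files", {
  root <- withr::local_tempdir()
  d <- make_experiment_dir(root)
  out <- withr::local_tempdir()
  res <- suppressMessages(
    autoplot_lifespan(d, out_dir = out, write_data = TRUE, quiet = TRUE))
  expect_s3_class(res, "experiment_result")
  expect_equal(res$title, "daf-2_vs_N2")
  expect_true(file.exists(res$main_plot_path))
  # strong lifespan extension: the individual comparison plot exists
  p <- res$reports$p_value[res$reports$condition == "daf-2 RNAi"]
  expect_lt(p, 0.05)
  expect_named(res$individual_plot_paths, "daf-2 RNAi")
  expect_true(file.exists(res$individual_plot_paths[["daf-2 RNAi"]]))
  # summary CSV columns and write-outs
  expect_true(all(file.exists(res$data_out_paths)))
  summ <- readr::read_csv(res$data_out_paths[["summary"]],
                          show_col_types = FALSE)
  expect_named(summ, c("condition", "n", "mean_lifespan", "median_lifespan",
                       "statistic", "p_value", "stars"))
})

test_that("legend and summary CSV agree on n, mean and p (single source)", {
  root <- withr::local_tempdir()
  d <- make_experiment_dir(root)
  res <- suppressMessages(autoplot_lifespan(d, return_data = TRUE, quiet = TRUE))
  leg <- res$legend
  summ <- res$summary[match(leg$condition, res$summary$condition), ]
  expect_equal(leg$n, summ$n)
  expect_equal(leg$mean_lifespan, summ$mean_lifespan)
  expect_equal(leg$p_value, summ$p_value)
  expect_equal(leg$stars, summ$stars)
  # and the rendered legend text embeds the same numbers
  for (k in seq_len(nrow(leg))) {
    expect_match(res$svg_main, sprintf("n=%d", leg$n[k]), fixed = TRUE)
  }
})

test_that("return_data returns the analysis without touching the disk", {
  root <- withr::local_tempdir()
  d <- make_experiment_dir(root)
  before <- list.files(d, recursive = TRUE)
  res <- suppressMessages(autoplot_lifespan(d, return_data = TRUE, quiet = TRUE))
  expect_identical(list.files(d, recursive = TRUE), before)
  expect_null(res$main_plot_path)
  expect_s3_class(res$km_data, "tbl_df")
  expect_gt(nrow(res$km_data), 0)
})

test_that("autoplot runs are byte-deterministic end to end", {
  root <- withr::local_tempdir()
  d <- make_experiment_dir(root)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressMessages(autoplot_lifespan(d, out_dir = out1, write_data = TRUE, quiet = TRUE))
  suppressMessages(autoplot_lifespan(d, out_dir = out2, write_data = TRUE, quiet = TRUE))
  files <- list.files(out1)
  expect_identical(files, list.files(out2))
  for (f in files) {
    a <- readBin(file.path(out1, f), "raw", file.size(file.path(out1, f)))
    b <- readBin(file.path(out2, f), "raw", file.size(file.path(out2, f)))
    expect_identical(a, b)
  }
})

test_that("multiple sheets pool into one experiment; control conflicts error", {
  root <- withr::local_tempdir()
  d <- file.path(root, "pooled")
  dir.create(d)
  s1 <- demo_sheet()
  write_count_sheet(s1, file.path(d, "a.csv"))
  # second sheet adds a condition plus more control worms, same control label
  s2 <- count_sheet(
    data.frame(condition = c("sod-3", "sod-3", "sod-3", "N2", "N2"),
               day = c(0, 6, 12, 0, 9),
               alive = c(6, 3, 0, 4, 0),
               died = c(0, 3, 3, 0, 4),
               censored = c(0, 0, 0, 0, 0)),
    control = "N2"
  )
  write_count_sheet(s2, file.path(d, "b.csv"))
  res <- suppressMessages(autoplot_lifespan(d, return_data = TRUE, quiet = TRUE))
  expect_setequal(res$reports$condition, c("N2", "daf-2 RNAi", "sod-3"))
  expect_equal(res$reports$n[res$reports$condition == "N2"], 14)  # 10 + 4 pooled

  bad <- file.path(root, "conflict")
  dir.create(bad)
  write_count_sheet(s1, file.path(bad, "a.csv"))
  s3 <- demo_sheet()
  s3$control <- "daf-2 RNAi"
  write_count_sheet(s3, file.path(bad, "b.csv"))
  expect_error(suppressMessages(autoplot_lifespan(bad, return_data = TRUE, quiet = TRUE)),
               "control", class = "wormspan_validation_error")
})

test_that("manualplot honors title, colors and x limits", {
  table <- convert_counts(demo_sheet())
  res <- manualplot_lifespan(table, title = "Figure 2A",
                             colors = c("N2" = "#336699"), quiet = TRUE)
  expect_equal(res$title, "Figure 2A")
  expect_match(res$svg_main, ">Figure 2A</text>", fixed = TRUE)
  expect_match(res$svg_main, "stroke=\"#336699\"", fixed = TRUE)
  # unspecified conditions fall back to the sheet/default colors
  expect_match(res$svg_main, "stroke=\"#D55E00\"", fixed = TRUE)

  # x limits excluding every event are rejected
  expect_error(manualplot_lifespan(table, x_limits = c(100, 200)),
               class = "wormspan_argument_error")
  expect_error(manualplot_lifespan(table, x_limits = c(0, 1)),
               class = "wormspan_argument_error")
})

test_that("batch processing logs failures without aborting the rest", {
  parent <- withr::local_tempdir()
  make_experiment_dir(parent, "exp_one", seed = 21)
  make_experiment_dir(parent, "exp_two", seed = 22)
  corrupt <- file.path(parent, "exp_bad")
  dir.create(corrupt)
  writeLines(c("#control: N2", "condition,day,alive,died,censored",
               "N2,0,10,0,0", "N2,5,9,4,0"), file.path(corrupt, "sheet.csv"))
  out <- withr::local_tempdir()
  msgs <- capture.output(
    res <- batch_autoplot(parent, out_dir = out, quiet = TRUE),
    type = "message"
  )
  expect_length(res, 3)
  expect_equal(attr(res, "n_failed"), 1)
  expect_s3_class(res[["exp_bad"]], "wormspan_failure")
  expect_true(any(grepl("FAILED 'exp_bad'", msgs)))
  # two successful experiments produced two distinctly titled main plots
  svgs <- list.files(out, pattern = "^exp_(one|two)\\.svg$")
  expect_setequal(svgs, c("exp_one.svg", "exp_two.svg"))
  expect_match(readLines(file.path(out, "exp_one.svg"), n = 30) |> paste(collapse = ""),
               ">exp_one</text>", fixed = TRUE)

  # empty parent is an input error
  empty <- withr::local_tempdir()
  expect_error(batch_autoplot(empty, quiet = TRUE), class = "wormspan_io_error")
})

test_that("missing sheets and missing control are clear input errors", {
  d <- withr::local_tempdir()
  expect_error(autoplot_lifespan(d), class = "wormspan_io_error")
  writeLines(c("condition,day,alive,died,censored", "N2,0,5,0,0"),
             file.path(d, "s.csv"))
  expect_error(suppressMessages(autoplot_lifespan(d, return_data = TRUE)),
               "control", class = "wormspan_validation_error")
})
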