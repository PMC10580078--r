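test_that("canonical CSV sheets read with metadata and pass validation", {
  path <- write_demo_csv()
  sheet <- read_count_sheet(path)
  expect_s3_class(sheet, "count_sheet")
  expect_equal(nrow(sheet$data), 6)
  expect_equal(sheet$control, "N2")
  expect_equal(sheet$experiment_name, "demo")
  expect_equal(sheet$temperature_c, 20)
  expect_equal(sheet$researchers, c("AB", "CD"))
  expect_equal(sheet$colors, c("daf-2 RNAi" = "#D55E00"))
})

test_that("xlsx sheets map columns A-E to the same contract", {
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_demo_xlsx(path)
  sheet <- read_count_sheet(path)
  expect_equal(sheet$control, "N2")
  expect_equal(sheet$data, demo_sheet()$data)
  expect_equal(sheet$temperature_c, 20)
})

test_that("format and validation errors are specific", {
  # missing required column
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#control: N2", "condition,day,alive,died",
               "N2,0,10,0"), p)
  expect_error(read_count_sheet(p), "censored",
               class = "wormspan_format_error")

  # bookkeeping violation names condition and day
  bad <- demo_sheet_lines()
  bad[bad == "N2,5,6,4,0"] <- "N2,5,7,4,0"
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, p2)
  expect_error(read_count_sheet(p2), "N2.*day 5",
               class = "wormspan_validation_error")

  # unknown control
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sub("#control: N2", "#control: CB1370", demo_sheet_lines()), p3)
  expect_error(read_count_sheet(p3), "CB1370",
               class = "wormspan_validation_error")

  # empty file
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), p4)
  expect_error(read_count_sheet(p4), "empty",
               class = "wormspan_format_error")

  # events at day 0 are impossible (times must be positive)
  expect_error(
    count_sheet(data.frame(condition = "N2", day = c(0, 3),
                           alive = c(9, 6), died = c(1, 3), censored = c(0, 0)),
                control = "N2"),
    "day 0", class = "wormspan_validation_error"
  )

  # days must strictly increase
  expect_error(
    count_sheet(data.frame(condition = "N2", day = c(0, 3, 3),
                           alive = c(10, 8, 6), died = c(0, 2, 2),
                           censored = c(0, 0, 0)),
                control = "N2"),
    "strictly increasing", class = "wormspan_validation_error"
  )
})

test_that("convert_counts expands counts and censors end-of-assay survivors", {
  sheet <- demo_sheet()
  table <- convert_counts(sheet)
  n2 <- dplyr::filter(table$events, condition == "N2")
  expect_equal(sum(n2$status == "DEATH" & n2$time == 5), 4)
  expect_equal(sum(n2$status == "DEATH" & n2$time == 10), 5)
  expect_equal(sum(n2$status == "CENSORED" & n2$time == 10), 1)
  expect_equal(nrow(n2), 10)

  # survivors at the last observation become CENSORED there
  s2 <- count_sheet(
    data.frame(condition = "x", day = c(0, 10, 20),
               alive = c(5, 2, 2), died = c(0, 3, 0), censored = c(0, 0, 0)),
    control = "x"
  )
  ev <- convert_counts(s2)$events
  expect_equal(sum(ev$status == "CENSORED" & ev$time == 20), 2)
  expect_equal(nrow(ev), 5)

  # degenerate: no deaths at all -> everything censored at the final day
  s3 <- count_sheet(
    data.frame(condition = "x", day = c(0, 15),
               alive = c(4, 4), died = c(0, 0), censored = c(0, 0)),
    control = "x"
  )
  ev3 <- convert_counts(s3)$events
  expect_true(all(ev3$status == "CENSORED" & ev3$time == 15))
  expect_equal(nrow(ev3), 4)
})

test_that("conversion conserves worms and is order-stable on random sheets", {
  for (seed in 1:12) {
    sheet <- random_sheet(seed)
    table <- convert_counts(sheet)
    initial <- sheet$data |>
      dplyr::group_by(condition) |>
      dplyr::summarize(n0 = alive[1] + died[1] + censored[1], .groups = "drop")
    got <- table$events |>
      dplyr::count(condition, name = "n_records")
    joined <- dplyr::inner_join(initial, got, by = "condition")
    expect_equal(joined$n0, joined$n_records)
    # deterministic and sorted
    expect_identical(table$events, convert_counts(sheet)$events)
    expect_identical(
      table$events,
      dplyr::arrange(table$events, condition, time, status)
    )
  }
})

test_that("event-table CSV round-trip is exact and byte-stable", {
  table <- convert_counts(demo_sheet())
  p <- withr::local_tempfile(fileext = ".csv")
  write_event_table(table, p)
  back <- read_event_table(p)
  expect_equal(back$events, table$events)
  expect_equal(back$control, table$control)
  expect_equal(back$temperature_c, table$temperature_c)
  expect_equal(back$researchers, table$researchers)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_event_table(back, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))

  # header + one line per record
  lines <- readLines(p)
  data_lines <- lines[!startsWith(lines, "#")]
  expect_length(data_lines, nrow(table$events) + 1)

  # empty table -> header-only body
  empty <- event_table(tibble::tibble(condition = character(),
                                      time = numeric(), status = character()),
                       control = "none")
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_event_table(empty, p3)
  body <- readLines(p3)
  expect_equal(body[!startsWith(body, "#")], "condition,time,status")
  expect_equal(nrow(read_event_table(p3)$events), 0)
})

test_that("bad status tokens are rejected with the accepted list", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#control: a", "condition,time,status", "a,3,dead"), p)
  expect_error(read_event_table(p), "DEATH, CENSORED",
               class = "wormspan_format_error")
})

test_that("ods reading reports the missing adapter package", {
  p <- withr::local_tempfile(fileext = ".ods")
  writeLines("placeholder", p)
  if (requireNamespace("readODS", quietly = TRUE)) {
    expect_error(read_count_sheet(p))  # not a real ods file
  } else {
    expect_error(read_count_sheet(p), "readODS",
                 class = "wormspan_io_error")
  }
})
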