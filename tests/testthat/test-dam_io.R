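test_that("well-formed monitor rows round-trip through the reader", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_toy_monitor(p,
                    counts_by_row = list(c(1, 0, 3), c(0, 2, 0), c(5, 5, 5)),
                    dates = rep("9 Aug 21", 3),
                    times = c("08:00:00", "08:01:00", "08:02:00"))
  r <- read_dam_monitor(p)
  expect_equal(nrow(r), 3L)
  expect_equal(r$ch01, c(1L, 0L, 5L))
  expect_equal(r$ch02, c(0L, 2L, 5L))
  expect_equal(r$ch03, c(3L, 0L, 5L))
  expect_true(all(r$valid))
  expect_equal(as.numeric(diff(r$datetime), units = "mins"), c(1, 1))
})

test_that("malformed rows are rejected with their line number", {
  p <- withr::local_tempfile(fileext = ".txt")
  ok <- paste(c(1, "9 Aug 21", "08:00:00", 1, rep(0, 6), rep(0, 32)),
              collapse = "\t")
  short <- paste(c(2, "9 Aug 21", "08:01:00", 1, rep(0, 6), rep(0, 30)),
                 collapse = "\t")
  writeLines(c(ok, short), p)
  expect_error(read_dam_monitor(p), "line 2")
})

test_that("non-monotone timestamps and missing files are errors", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_toy_monitor(p, list(0, 0), rep("9 Aug 21", 2),
                    c("08:01:00", "08:00:00"))
  expect_error(read_dam_monitor(p), "strictly increasing")
  expect_error(read_dam_monitor(file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("invalid-status readings are retained but flagged, and their minutes go missing", {
  p <- withr::local_tempfile(fileext = ".txt")
  lines <- c(
    paste(c(1, "9 Aug 21", "08:00:00", 1, rep(0, 6), 2, rep(0, 31)), collapse = "\t"),
    paste(c(2, "9 Aug 21", "08:01:00", 51, rep(0, 6), 9, rep(0, 31)), collapse = "\t"),
    paste(c(3, "9 Aug 21", "08:02:00", 1, rep(0, 6), 4, rep(0, 31)), collapse = "\t")
  )
  writeLines(lines, p)
  r <- read_dam_monitor(p)
  expect_equal(r$valid, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(r), 3L)
  b <- bin_to_minutes(r, 1)
  expect_equal(b$count, c(2L, NA_integer_, 4L))
})

test_that("sub-minute readings sum into their containing minute", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_toy_monitor(p, list(2, 3, 7), rep("9 Aug 21", 3),
                    c("08:00:10", "08:00:40", "08:01:30"))
  b <- bin_to_minutes(read_dam_monitor(p), 1)
  expect_equal(b$count, c(5L, 7L))
})

test_that("1-minute cadence binning is the identity and skipped minutes are missing", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_toy_monitor(p, list(1, 2, 4), rep("9 Aug 21", 3),
                    c("08:00:00", "08:01:00", "08:03:00"))
  b <- bin_to_minutes(read_dam_monitor(p), 1)
  expect_equal(b$count, c(1L, 2L, NA_integer_, 4L))
  expect_error(bin_to_minutes(read_dam_monitor(p), 33), "1\\.\\.32")
})

test_that("10-second cadence matches brute-force per-minute sums and conserves counts", {
  set.seed(11)
  n <- 5 * 6 # 5 minutes at 10-s cadence
  secs <- seq(0, by = 10, length.out = n)
  counts <- rpois(n, 2)
  p <- withr::local_tempfile(fileext = ".txt")
  write_toy_monitor(p, as.list(counts), rep("9 Aug 21", n),
                    sprintf("08:%02d:%02d", secs %/% 60, secs %% 60))
  b <- bin_to_minutes(read_dam_monitor(p), 1)
  expected <- as.integer(tapply(counts, secs %/% 60, sum))
  expect_equal(b$count, expected)
  expect_equal(sum(b$count), sum(counts)) # sum conservation
})

test_that("annotation labels boundary minutes by calendar day role and ZT", {
  des <- experiment_design("2021-08-09", "2021-08-10", "2021-08-11",
                           lights_on = "08:00")
  mins <- as.POSIXct(c("2021-08-10 07:59:00", "2021-08-10 08:00:00"),
                     tz = "UTC")
  binned <- data.table::data.table(minute = mins, count = c(0L, 1L))
  a <- suppressWarnings(annotate_minutes(binned, des, fly_id = "f1"))
  expect_equal(a$day_role, c("activation", "activation"))
  expect_equal(a$zt_minute, c(1439L, 0L))
  expect_equal(a$phase, c("DP", "LP"))
})

test_that("a full 3-day recording yields 720 LP and 720 DP minutes per day", {
  scr <- toy_screen(n_drivers = 1, flies = 1, seed = 5)
  act <- scr$activity[fly_id == scr$activity$fly_id[1]]
  tab <- act[, .N, by = .(day_role, phase)]
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$N == 720L))
  # phase partition: LP + DP minutes = minutes present each day
  per_day <- act[, .N, by = day_role]
  expect_true(all(per_day$N == 1440L))
})

test_that("minutes outside the design days are dropped", {
  des <- experiment_design("2021-08-09", "2021-08-10", "2021-08-11")
  mins <- as.POSIXct(c("2021-08-08 12:00:00", "2021-08-09 12:00:00"),
                     tz = "UTC")
  binned <- data.table::data.table(minute = mins, count = c(1L, 1L))
  a <- suppressWarnings(annotate_minutes(binned, des, fly_id = "f1"))
  expect_equal(nrow(a), 1L)
  expect_equal(a$day_role, "baseline")
})

test_that("canonical files round-trip byte-identically", {
  scr <- toy_screen(n_drivers = 1, flies = 2, seed = 9)
  d1 <- withr::local_tempdir()
  scr2 <- simulate_screen(scr$config, dir = d1)
  f <- scr2$paths$monitors[[1]]
  r <- read_dam_monitor(f)
  f2 <- file.path(d1, "rewrite.txt")
  write_dam_monitor(r, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_equal(nrow(r), 3 * 1440)
  expect_true(!is.unsorted(r$datetime, strictly = TRUE))
})

test_that("simulator-written screens reload field-by-field through the io path", {
  cfg <- simulation_config(n_drivers = 2, flies_per_genotype = 2, seed = 21)
  d <- withr::local_tempdir()
  scr <- simulate_screen(cfg, dir = d)
  cm <- read_channel_map(scr$paths$channel_map)
  act <- load_dam_screen(scr$paths$monitors, cm, scr$design)
  mem <- scr$activity
  data.table::setorder(act, fly_id, minute)
  data.table::setorder(mem, fly_id, minute)
  expect_equal(act$count, mem$count)
  expect_equal(act$phase, mem$phase)
  expect_equal(act$day_role, mem$day_role)
  expect_equal(act$zt_minute, mem$zt_minute)
  expect_equal(act$genotype_role, mem$genotype_role)
})

test_that("dead-fly filter drops by recovery-day activity threshold", {
  act <- data.table::data.table(
    fly_id = rep(c("a", "b"), each = 3),
    day_role = rep(c("baseline", "activation", "recovery"), 2),
    count = c(5L, 5L, 0L, 5L, 5L, 3L)
  )
  d1 <- filter_dead_flies(act, 1)
  expect_equal(d1[fly_id == "a", keep], FALSE)
  expect_equal(d1[fly_id == "b", keep], TRUE)
  d0 <- filter_dead_flies(act, 0)
  expect_true(all(d0$keep)) # vacuous filter
  # 5 active recovery minutes under threshold 10 -> dropped
  act2 <- data.table::data.table(
    fly_id = "c", day_role = "recovery", count = c(rep(1L, 5), rep(0L, 20))
  )
  expect_false(filter_dead_flies(act2, 10)$keep)
})
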