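test_that("read_fixes types, sorts and de-duplicates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "fx.csv")

  # empty file with header
  writeLines("tag_id,time_utc_ms,x_m,y_m,std_m", p)
  expect_equal(nrow(read_fixes(p)), 0)

  # duplicates collapse to the first, shuffled input sorts identically
  df <- data.frame(tag_id = "t1", time_utc_ms = c(1000, 2000, 2000),
                   x_m = c(1, 2, 99), y_m = 0, std_m = 5)
  data.table::fwrite(df, p)
  fx <- read_fixes(p)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$x, c(1, 2))
  data.table::fwrite(df[c(3, 1, 2), ], p)
  fx_shuf <- read_fixes(p)
  expect_equal(fx_shuf$time_ms, c(1000, 2000))

  # missing column gives a schema error naming it
  data.table::fwrite(df[, -5], p)
  expect_error(read_fixes(p), "std_m")
})

test_that("accuracy and speed filters remove exactly the offending fixes", {
  # stds [10, 60, 20, 49, 51] with no movement: only the STD filter acts
  fx <- toy_fixes(c(10, 60, 20, 49, 51))
  out <- filter_fixes(fx)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "stage_counts"), c(std = 2, speed = 0))

  # 200 m in 10 s = 20 m/s: the later fix of the pair is removed
  fx2 <- toy_track(c(0, 200), c(0, 0), dt_s = 10)
  out2 <- filter_fixes(fx2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$x, 0)

  # a spike cannot shield its successor: speed recomputed vs last retained
  fx3 <- toy_track(c(0, 500, 20), c(0, 0, 0), dt_s = 10)
  out3 <- filter_fixes(fx3)
  expect_equal(out3$x, c(0, 20))

  # idempotence on clean input
  cfg <- sim_config(noise_sd_m = 0, seed = 1)
  tr <- simulate_night_track(2, cfg, seed = 2)
  cl <- filter_fixes(tr)
  expect_equal(nrow(cl), nrow(tr))
  again <- filter_fixes(cl)
  expect_equal(again[, c("time_ms", "x", "y")], cl[, c("time_ms", "x", "y")])
})

test_that("night segmentation applies closed-open local-time bounds", {
  # local = UTC + 2; build fixes at specific local clock times on 2021-03-10
  day0 <- as.numeric(as.Date("2021-03-10"))  # days since epoch
  at_local <- function(h, m = 0, day = day0)
    ((day * 86400 + h * 3600 + m * 60) - 2 * 3600) * 1000
  fx <- data.frame(
    tag_id = "t", x = 0, y = 0, std = 5,
    time_ms = c(at_local(16, 59), at_local(17, 0), at_local(5, 59, day0 + 1),
                at_local(6, 0, day0 + 1), at_local(12, 0)))
  out <- segment_nights(fx, utc_offset_h = 2)
  expect_equal(nrow(out), 2)   # 17:00 and 05:59 kept; 16:59, 06:00, noon out
  expect_equal(as.character(out$night_date),
               rep("2021-03-10", 2))

  # 24 h of continuous 8-s fixes: exactly the 13-h window is retained
  fx24 <- data.frame(tag_id = "t", x = 0, y = 0, std = 5,
                     time_ms = (day0 * 86400 + seq(0, 86399, by = 8)) * 1000)
  out24 <- segment_nights(fx24, utc_offset_h = 0)
  expect_equal(nrow(out24), 5850)
})

test_that("period labels follow the annual cycle with October-keyed winters", {
  expect_equal(assign_period(as.Date("2021-03-15")), "P1")
  expect_equal(assign_period(as.Date("2021-06-01")), "P2")
  expect_equal(assign_period(as.Date("2021-11-20")), "P3")
  py <- assign_period(as.Date(c("2021-01-10", "2020-10-05", "2021-05-31")),
                      with_year = TRUE)
  expect_equal(py$period, c("P3", "P3", "P1"))
  expect_equal(py$year, c(2020L, 2020L, 2021L))
})

test_that("age class flips at the first birthday and falls back to metadata", {
  md <- data.frame(individual = c("a", "b"),
                   hatch_date = as.Date(c("2020-04-01", NA)),
                   age_at_tagging = c("juvenile", "adult"),
                   stringsAsFactors = FALSE)
  expect_equal(assign_age_class("a", as.Date("2021-03-31"), md), "juvenile")
  expect_equal(assign_age_class("a", as.Date("2021-04-02"), md), "adult")
  expect_equal(assign_age_class("b", as.Date("1999-01-01"), md), "adult")
  md$age_at_tagging <- NULL
  expect_true(is.na(assign_age_class("b", as.Date("2021-01-01"), md)))
})

test_that("inclusion rules enforce strict night and period thresholds", {
  # one individual, 30 nights in one period: nights with exactly 1000 fixes
  # are dropped, 1001 kept
  mk_night <- function(ind, date, n) {
    d <- as.numeric(as.Date(date))
    data.frame(individual = ind, tag_id = "t", x = 0, y = 0, std = 5,
               time_ms = ((d * 86400 + 17 * 3600) + seq_len(n)) * 1000,
               night_date = as.Date(date), stringsAsFactors = FALSE)
  }
  nights <- do.call(rbind, c(
    lapply(1:26, function(i) mk_night("a", as.Date("2021-06-01") + i, 1001)),
    list(mk_night("a", as.Date("2021-06-28"), 1000))))
  res <- apply_inclusion_rules(nights, min_fixes = 1000, min_nights = 25)
  expect_equal(res$report$nights_below_min_fixes, 1)
  expect_equal(res$report$nights_out, 26)

  # 24 qualifying nights in a period: the whole individual-period is removed
  n24 <- do.call(rbind, lapply(1:24, function(i)
    mk_night("b", as.Date("2021-06-01") + i, 1001)))
  res24 <- apply_inclusion_rules(n24, min_fixes = 1000, min_nights = 25)
  expect_equal(nrow(res24$dataset), 0)
  expect_equal(res24$report$cells_below_min_nights, 1)

  # empty exclusion windows change nothing; a matching window drops nights
  res_w <- apply_inclusion_rules(nights, exclusion_windows =
    data.frame(individual = "zz", start = "2021-06-01", end = "2021-06-30"))
  expect_equal(res_w$dataset, res$dataset)
  res_x <- apply_inclusion_rules(nights, exclusion_windows =
    data.frame(individual = "a", start = "2021-06-02", end = "2021-06-05"))
  expect_equal(res_x$report$nights_excluded_window, 4)
})
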