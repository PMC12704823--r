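test_that("count cut-points classify on half-open bands with sleep precedence", {
  expect_equal(as.character(classify_epoch(c(0, 1999, 2000, 7499, 7500, 20000))),
               c("sb", "sb", "lpa", "lpa", "mvpa", "mvpa"))
  # sleep flag overrides the count bands
  expect_equal(as.character(classify_epoch(9000, sleep = TRUE)), "sleep")
  # non-wear minutes are not classified
  expect_true(is.na(classify_epoch(500, wear = FALSE)))
  expect_error(classify_epoch(-1), "non-negative")
  # every worn wake minute gets exactly one label
  set.seed(5)
  lab <- classify_epoch(runif(500, 0, 15000))
  expect_false(any(is.na(lab)))
})

test_that("summarize_day counts worn minutes per behavior", {
  d <- summarize_day(make_epoch_day(counts = rep(0, 1440)))
  expect_equal(d$sb_min, 1440)
  expect_equal(d$sleep_min + d$lpa_min + d$mvpa_min, 0)
  expect_equal(d$wear_hours, 24)

  e <- make_epoch_day(counts = rep(3000, 1440),
                      sleep = c(rep(TRUE, 480), rep(FALSE, 960)))
  d2 <- summarize_day(e)
  expect_equal(d2$sleep_min, 480)
  expect_equal(d2$lpa_min, 960)

  # minute conservation: behaviors + non-wear = epochs supplied
  e3 <- make_epoch_day(counts = runif(1000, 0, 10000),
                       wear = rep(c(TRUE, FALSE), c(700, 300)))
  d3 <- summarize_day(e3)
  expect_equal(d3$sleep_min + d3$sb_min + d3$lpa_min + d3$mvpa_min, 700)
  expect_equal(d3$wear_hours, 700 / 60)

  dup <- make_epoch_day(counts = rep(0, 10))
  dup$timestamp[2] <- dup$timestamp[1]
  expect_error(summarize_day(dup), "duplicate")
  two_days <- make_epoch_day(counts = rep(0, 10))
  two_days$timestamp[10] <- two_days$timestamp[10] + 86400
  expect_error(summarize_day(two_days), "one calendar day")
})

test_that("wear-validity rules apply the 16 h / 4 day thresholds exactly", {
  days <- tibble::tibble(
    date = as.Date("2020-01-06") + 0:3,
    sleep_min = 480, sb_min = 500, lpa_min = 300, mvpa_min = 40,
    wear_hours = c(17, 18, 16, 20)
  )
  f <- filter_valid_days(days)
  expect_equal(f$n_valid_days, 4)
  expect_true(f$participant_valid)

  just_short <- days[rep(1, 10), ]
  just_short$wear_hours <- 15.99
  f2 <- filter_valid_days(just_short)
  expect_equal(f2$n_valid_days, 0)
  expect_false(f2$participant_valid)

  three <- days[1:3, ]
  three$wear_hours <- 16
  f3 <- filter_valid_days(three)
  expect_equal(f3$n_valid_days, 3)
  expect_false(f3$participant_valid)
})

test_that("average_composition means, imputes zeros, and rescales to 1440", {
  same <- tibble::tibble(sleep_min = 450, sb_min = 580, lpa_min = 368,
                         mvpa_min = 42)[rep(1, 5), ]
  a <- average_composition(same)
  expect_equal(c(a$sleep_min, a$sb_min, a$lpa_min, a$mvpa_min),
               c(450, 580, 368, 42))

  two <- tibble::tibble(
    sleep_min = c(400, 500), sb_min = c(600, 560),
    lpa_min = c(400, 340), mvpa_min = c(40, 40)
  )
  a2 <- average_composition(two)
  m <- c(450, 580, 370, 40)  # arithmetic means, total 1440 already
  expect_equal(c(a2$sleep_min, a2$sb_min, a2$lpa_min, a2$mvpa_min), m)

  # 90 non-wear minutes: proportional rescale by 1440/1350 (hand computed)
  short <- tibble::tibble(sleep_min = 450, sb_min = 520, lpa_min = 340,
                          mvpa_min = 40)
  a3 <- average_composition(short)
  expect_equal(c(a3$sleep_min, a3$sb_min, a3$lpa_min, a3$mvpa_min),
               c(450, 520, 340, 40) * 1440 / 1350)

  # person-level zero gets the pseudo-minute before closure
  zero_mvpa <- tibble::tibble(sleep_min = 480, sb_min = 600, lpa_min = 360,
                              mvpa_min = 0)
  a4 <- average_composition(zero_mvpa)
  expect_gt(a4$mvpa_min, 0)
  expect_equal(a4$sleep_min / a4$sb_min, 480 / 600)
  expect_error(average_composition(zero_mvpa, zero_minutes = 0), "exactly 0")
})

test_that("a simulated minute stream recovers its generating expectations", {
  cfg <- minute_sim_config(seed = 21, n_days = 8, nonwear_gap_rate = 0)
  stream <- simulate_minute_stream(cfg)
  days <- summarize_days(stream)
  expect_equal(nrow(days), 8)
  expect_equal(days$sleep_min, rep(480, 8))
  expect_equal(days$wear_hours, rep(24, 8))
  # wake split near the configured proportions (960 wake min/day);
  # allow band leakage plus binomial noise
  wake_mean <- colMeans(days[, c("sb_min", "lpa_min", "mvpa_min")])
  expected <- 960 * cfg$wake_props
  expect_lt(max(abs(wake_mean - expected)), 25)
  # full pipeline accepts all days
  f <- filter_valid_days(days)
  expect_true(f$participant_valid)
  expect_equal(f$n_valid_days, 8)
})

test_that("heavy non-wear days fail the validity filter", {
  cfg <- minute_sim_config(seed = 22, n_days = 10, nonwear_gap_rate = 9)
  days <- summarize_days(simulate_minute_stream(cfg))
  # expected wear = 24 - 9 = 15 h < 16 h; most days invalid
  f <- filter_valid_days(days)
  expect_lt(f$n_valid_days, 4)
  expect_false(f$participant_valid)
})

test_that("process_epochs assembles participants and logs exclusions", {
  good <- simulate_minute_stream(minute_sim_config(seed = 31, n_days = 6))
  good$id <- "A"
  bad <- simulate_minute_stream(
    minute_sim_config(seed = 32, n_days = 6, nonwear_gap_rate = 12)
  )
  bad$id <- "B"
  tu <- process_epochs(dplyr::bind_rows(good, bad))
  expect_equal(nrow(tu), 2)
  expect_true(tu$valid[tu$id == "A"])
  expect_false(tu$valid[tu$id == "B"])
  a <- tu[tu$id == "A", ]
  expect_equal(a$sleep_min + a$sb_min + a$lpa_min + a$mvpa_min, 1440)
  excl <- attr(tu, "exclusions")
  expect_equal(excl$id, "B")
  expect_match(excl$reason, "valid days")
})

test_that("epoch CSV round-trips", {
  stream <- simulate_minute_stream(minute_sim_config(seed = 41, n_days = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(stream, path)
  back <- read_epoch_csv(path)
  expect_equal(back$counts, stream$counts, tolerance = 1e-9)
  expect_identical(back$wear, stream$wear)
  expect_identical(back$sleep, stream$sleep)
  expect_equal(summarize_days(back), summarize_days(stream))
})
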