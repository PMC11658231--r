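test_that("ENMO cut-points classify with inclusive lower bounds", {
  ep <- make_epochs(c(0, 39.9, 40, 99.9, 100, 399.9, 400, 1000))
  cl <- classify_epochs(ep)
  expect_equal(as.character(cl$band),
               c("inactive", "inactive", "lpa", "lpa", "mvpa", "mvpa",
                 "mvpa", "mvpa"))
  expect_equal(cl$vigorous, c(F, F, F, F, F, F, T, T))
  expect_error(enmo_band(c(10, -1)), "non-negative")
  expect_error(enmo_band(c(10, NaN)), "non-negative")
})

test_that("duration_in_window counts epochs times epoch length", {
  ep <- make_epochs(rep(60, 12)) # 12 LPA epochs = 60 s
  expect_equal(duration_in_window(ep, T0 - 5, T0 + 60, "lpa"), 1 / 60)
  expect_equal(duration_in_window(ep, T0 + 3600, T0 + 7200, "lpa"), 0)
  sat <- make_epochs(rep(150, 1440)) # 1440 MVPA epochs = 2 h
  expect_equal(duration_in_window(sat, T0 - 5, T0 + 7200, "mvpa"), 2)
})

test_that("band durations partition wear time and windows are additive", {
  set.seed(21)
  ep <- make_epochs(runif(2000, 0, 300))
  for (i in 1:20) {
    a <- T0 + runif(1, -600, 8000)
    b <- a + runif(1, 0, 5000)
    tot <- sum(ep$timestamp > a & ep$timestamp <= b) * 5 / 3600
    parts <- sapply(c("inactive", "lpa", "mvpa"), function(bd)
      duration_in_window(ep, a, b, bd))
    expect_equal(sum(parts), tot, tolerance = 1e-12)
    mid <- a + (b - a) / 2
    expect_equal(duration_in_window(ep, a, mid, "lpa") +
                   duration_in_window(ep, mid, b, "lpa"),
                 duration_in_window(ep, a, b, "lpa"), tolerance = 1e-12)
  }
})

test_that("time shifts leave all activity features unchanged", {
  set.seed(22)
  ep <- make_epochs(runif(17280 * 2, 0, 200), start = T0 - 86400)
  f1 <- meal_activity(ep, T0 + 3600)
  shift <- 987 * 60
  ep2 <- dplyr::mutate(ep, timestamp = timestamp + shift)
  f2 <- meal_activity(ep2, T0 + 3600 + shift)
  expect_equal(f1, f2)
})

test_that("a constructed 15-min MVPA bout lands in the postprandial window", {
  # inactive everywhere except 15 min of MVPA starting 10 min post-meal
  n <- 86400 / 5 * 2
  enmo <- rep(10, n)
  start <- T0 - 86400
  bout_idx <- which(
    seq(0, by = 5, length.out = n) >= (86400 + 600) &
      seq(0, by = 5, length.out = n) < (86400 + 600 + 900)
  )
  enmo[bout_idx] <- 200
  ep <- make_epochs(enmo, start = start)
  f <- meal_activity(ep, T0)
  expect_equal(f$pp_mvpa_h, 0.25)
  expect_equal(f$pp_lpa_h, 0)
  expect_equal(f$daily_mvpa_h, 0)
  # the same bout before the meal counts only toward the daily window
  enmo2 <- rep(10, n)
  enmo2[bout_idx - 7200 / 5] <- 200 # now 1h50m *before* the meal... still post
  f2 <- meal_activity(make_epochs(enmo2, start = start), T0 + 3 * 3600)
  expect_equal(f2$pp_mvpa_h, 0)
  expect_equal(f2$daily_mvpa_h, 0.25)
})

test_that("windows beyond the series span give missing features", {
  ep <- make_epochs(rep(10, 720), start = T0) # one hour of epochs
  f <- meal_activity(ep, T0 + 1800)
  expect_true(is.na(f$pp_lpa_h))   # post window exceeds span
  expect_true(is.na(f$daily_lpa_h)) # daily window starts before span
})

test_that("sleep_before picks the latest wake within 24 h", {
  sl <- tibble::tibble(
    participant_id = "P1",
    onset = utc(c("2023-01-01 23:30", "2023-01-02 13:00")),
    wake = utc(c("2023-01-02 06:00", "2023-01-02 13:45"))
  )
  expect_equal(sleep_before(sl, utc("2023-01-02 08:00")), 6.5)
  # nap after main sleep: the later wake wins
  expect_equal(sleep_before(sl, utc("2023-01-02 19:00")), 0.75)
  expect_true(is.na(sleep_before(sl, utc("2023-01-04 08:00"))))
  bad <- tibble::tibble(participant_id = "P1",
                        onset = utc(c("2023-01-01 23:00", "2023-01-02 01:00")),
                        wake = utc(c("2023-01-02 02:00", "2023-01-02 05:00")))
  expect_error(sleep_before(bad, utc("2023-01-02 08:00")), "overlap")
})

test_that("cohort-level activity features agree with the per-meal operations", {
  set.seed(23)
  ep <- dplyr::bind_rows(
    make_epochs(runif(17280 * 2, 0, 250), start = T0 - 86400, pid = "A"),
    make_epochs(runif(17280 * 2, 0, 250), start = T0 - 86400, pid = "B")
  )
  sl <- tibble::tibble(
    participant_id = c("A", "B"),
    onset = utc(c("2023-01-01 23:30", "2023-01-02 00:15")),
    wake = utc(c("2023-01-02 05:30", "2023-01-02 06:10"))
  )
  meals <- tibble::tibble(
    meal_id = c("m1", "m2", "m3"),
    participant_id = c("A", "A", "B"),
    meal_timestamp = c(T0, T0 + 6 * 3600, T0 + 3600)
  )
  feats <- meal_activity_features(meals, ep, sl)
  for (i in 1:3) {
    ref <- meal_activity(ep[ep$participant_id == meals$participant_id[i], ],
                         meals$meal_timestamp[i])
    expect_equal(feats$pp_lpa_h[i], ref$pp_lpa_h)
    expect_equal(feats$pp_mvpa_h[i], ref$pp_mvpa_h)
    expect_equal(feats$daily_lpa_h[i], ref$daily_lpa_h)
    expect_equal(feats$daily_mvpa_h[i], ref$daily_mvpa_h)
    expect_equal(feats$sleep_h[i],
                 sleep_before(sl[sl$participant_id == meals$participant_id[i], ],
                              meals$meal_timestamp[i]))
  }
})

test_that("sparse wear inside a window marks features missing", {
  set.seed(24)
  ep <- make_epochs(runif(17280 * 2, 0, 200), start = T0 - 86400)
  # remove half of the postprandial window's epochs
  drop <- ep$timestamp > T0 & ep$timestamp <= T0 + 3600
  sparse <- ep[!drop, ]
  f <- meal_activity(sparse, T0)
  expect_true(is.na(f$pp_lpa_h))
  expect_false(is.na(f$daily_lpa_h))
  # the relaxed threshold admits the window again
  f2 <- meal_activity(sparse, T0, min_wear_frac = 0.4)
  expect_false(is.na(f2$pp_lpa_h))
})
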