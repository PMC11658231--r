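test_that("meal timestamps resolve against the response date", {
  resp <- dplyr::bind_rows(
    ema_row("P1", "2021-06-02 08:40", "after_last_ema_yesterday", "23:30"),
    ema_row("P1", "2021-06-02 08:40:01", "since_waking", "07:15"),
    ema_row("P1", "2021-06-03 08:40", "after_last_ema_yesterday", "00:30"),
    ema_row("P1", "2021-06-02 13:20", "since_last_prompt", "12:45")
  )
  meals <- resolve_meal_timestamps(resp)
  expect_equal(sort(meals$meal_timestamp), sort(utc(c(
    "2021-06-01 23:30", # evening clock + yesterday occasion -> day before
    "2021-06-02 07:15", # since waking -> response date
    "2021-06-03 00:30", # after midnight, before sleep -> response date
    "2021-06-02 12:45"
  ))))
})

test_that("unparseable clock times and duplicate reports are dropped with warnings", {
  resp <- dplyr::bind_rows(
    ema_row("P1", "2021-06-02 08:40", "since_waking", "07:15"),
    ema_row("P1", "2021-06-02 08:41", "since_waking", "25:61"),
    ema_row("P1", "2021-06-02 08:42", "since_last_prompt", "07:15")
  )
  w <- capture_warnings(m <- resolve_meal_timestamps(resp))
  expect_match(w, "unparseable", all = FALSE)
  expect_match(w, "duplicate", all = FALSE)
  expect_equal(nrow(m), 1)
})

test_that("time-of-day categories use half-open 6-h intervals", {
  t <- utc(sprintf("2023-01-02 %s", c("05:59", "06:00", "11:59", "12:00",
                                      "17:59", "18:00", "23:59")))
  expect_equal(as.character(meal_time_category(t)),
               c(NA, "morning_0600_1200", "morning_0600_1200",
                 "afternoon_1200_1800", "afternoon_1200_1800",
                 "evening_1800_2400", "evening_1800_2400"))
})

test_that("the three meal-level rules are applied independently", {
  cgm <- flat_trace(5.5, start = utc("2023-01-02 08:00"), pre_h = 6, post_h = 18)
  meals <- tibble::tibble(
    meal_id = c("a", "b", "c"),
    participant_id = "P1",
    meal_timestamp = utc(c("2023-01-02 08:00", "2023-01-02 10:00",
                           "2023-01-02 05:15"))
  )
  q <- qualify_meals(meals, cgm)
  expect_true(q$qualified[q$meal_id == "a"])
  expect_equal(q$failure_reasons[q$meal_id == "a"], "")
  expect_false(q$qualified[q$meal_id == "b"]) # 2 h after meal a
  expect_true(q$prior_intake_within_2p5h[q$meal_id == "b"])
  expect_false(q$qualified[q$meal_id == "c"]) # 05:30 outside 06:00-24:00
  expect_true(q$outside_0600_2400[q$meal_id == "c"])
})

test_that("the 2.5 h prior-intake window is closed on the left, open at t", {
  cgm <- flat_trace(5.5, start = utc("2023-01-02 06:00"), pre_h = 4, post_h = 20)
  meals <- tibble::tibble(
    meal_id = c("a", "b", "c"),
    participant_id = "P1",
    meal_timestamp = utc(c("2023-01-02 08:00", "2023-01-02 10:30",
                           "2023-01-02 13:01"))
  )
  q <- qualify_meals(meals, cgm)
  expect_true(q$prior_intake_within_2p5h[q$meal_id == "b"]) # exactly 2.5 h
  expect_false(q$prior_intake_within_2p5h[q$meal_id == "c"]) # 2 h 31 min
})

test_that("disqualified meals still count as prior intake", {
  cgm <- flat_trace(5.5, start = utc("2023-01-02 05:00"), pre_h = 4, post_h = 20)
  meals <- tibble::tibble(
    meal_id = c("early", "breakfast"),
    participant_id = "P1",
    meal_timestamp = utc(c("2023-01-02 05:45", "2023-01-02 07:30"))
  )
  q <- qualify_meals(meals, cgm)
  expect_false(q$qualified[q$meal_id == "early"])
  expect_true(q$prior_intake_within_2p5h[q$meal_id == "breakfast"])
})

test_that("missing or sparse CGM fails coverage", {
  meals <- tibble::tibble(meal_id = c("a", "b"), participant_id = c("P1", "P2"),
                          meal_timestamp = utc("2023-01-02 09:00"))
  cgm <- flat_trace(5.5, start = utc("2023-01-02 06:00"), pre_h = 0, post_h = 12)
  q <- qualify_meals(meals, cgm) # P2 has no trace at all
  expect_true(q$no_cgm_coverage[q$participant_id == "P2"])
  expect_false(q$no_cgm_coverage[q$participant_id == "P1"])
  # drop readings in the postprandial window below the 80% rule
  sparse <- dplyr::filter(cgm, !(timestamp > utc("2023-01-02 09:00") &
                                   timestamp <= utc("2023-01-02 10:00")))
  q2 <- qualify_meals(meals[1, ], sparse)
  expect_true(q2$no_cgm_coverage)
})

test_that("qualification is order-independent", {
  set.seed(31)
  cgm <- flat_trace(5.5, start = utc("2023-01-02 06:00"), pre_h = 6, post_h = 18)
  meals <- tibble::tibble(
    meal_id = sprintf("m%d", 1:6),
    participant_id = "P1",
    meal_timestamp = utc("2023-01-02 06:30") + c(0, 1.5, 4, 7, 9, 12) * 3600
  )
  q1 <- qualify_meals(meals, cgm)
  q2 <- qualify_meals(meals[sample(6), ], cgm)
  expect_equal(dplyr::arrange(q1, meal_id), dplyr::arrange(q2, meal_id))
})

test_that("participants need at least three qualifying meals", {
  qual <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), c(4, 3, 5)),
    qualified = c(rep(TRUE, 4), rep(TRUE, 3), rep(c(TRUE, FALSE), c(2, 3)))
  )
  r <- filter_participants(qual)
  expect_true(r$retained[r$participant_id == "A"])
  expect_true(r$retained[r$participant_id == "B"])  # exactly 3: inclusive
  expect_false(r$retained[r$participant_id == "C"]) # only 2 qualified
  empty <- filter_participants(qual[0, ])
  expect_equal(nrow(empty), 0)
})
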