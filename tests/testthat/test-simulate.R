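test_that("the same configuration and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_participants = 3, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$ema_responses, b$ema_responses)
  expect_identical(a$glucose_traces, b$glucose_traces)
  expect_identical(a$epoch_series, b$epoch_series)
  expect_identical(a$sleep_windows, b$sleep_windows)
  expect_identical(a$meal_truth, b$meal_truth)
})

test_that("adding participants does not perturb existing ones", {
  small <- simulate_cohort(sim_config(n_participants = 2, seed = 78))
  big <- simulate_cohort(sim_config(n_participants = 4, seed = 78))
  keep <- function(df) df[df$participant_id %in% c("P001", "P002"), ]
  expect_identical(keep(big$ema_responses), small$ema_responses)
  expect_identical(keep(big$glucose_traces), small$glucose_traces)
  expect_identical(keep(big$meal_truth), small$meal_truth)
})

test_that("glucose traces span the configured study period", {
  co <- simulate_cohort(sim_config(n_participants = 2, n_days = 9, seed = 79))
  spans <- co$glucose_traces |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(span_h = as.numeric(max(timestamp) - min(timestamp),
                                         units = "hours"),
                     step = median(as.numeric(diff(timestamp), units = "mins")))
  expect_true(all(spans$span_h >= 9 * 24))
  expect_true(all(spans$step == 15))
})

test_that("configuration and truth validation catches bad inputs", {
  expect_error(sim_config(ema_windows = list(c(8, 11), c(10, 12))),
               "configuration error")
  expect_error(sim_config(ema_windows = list(c(5, 7))), "configuration error")
  expect_error(ground_truth(within_effects = c(pizza = 5)), "not canonical")
  expect_error(ground_truth(residual_sd = -1), "non-negative")
  expect_error(intended_iauc(c(pizza = 1), ground_truth()), "unknown exposure")
})

test_that("the bump kernel is a unit-area non-negative curve peaking near 45 min", {
  u <- seq(0, 130, by = 0.01)
  k <- gamma_bump_kernel(u)
  expect_true(all(k >= 0))
  expect_equal(k[u == 0], 0)
  expect_true(all(k[u > 120] == 0))
  expect_equal(sum(k) * 0.01, 1, tolerance = 1e-3)
  expect_equal(u[which.max(k)], 45, tolerance = 1)
})

test_that("intended_iauc implements the linear predictor", {
  tr0 <- ground_truth(intercept = 0)
  expect_equal(intended_iauc(c(refined_grains = 0), tr0, noise = 0), 0)
  expect_equal(intended_iauc(c(refined_grains = 1), tr0, noise = 0), 46.2)
  expect_equal(intended_iauc(c(sleep_h = 2), tr0, noise = 0,
                             time_category = "afternoon_1200_1800"),
               max(0, 54.4 - 2 * 2.7))
  # the floor at zero
  expect_equal(intended_iauc(c(dairy = 1), tr0, noise = -10), 0)
})

test_that("recomputing iAUC from a clean trace recovers the intended value", {
  cfg <- sim_config(n_participants = 4, seed = 80, cgm_noise_sd = 0,
                    circadian_amp = 0, missingness = list(cgm = 0, epochs = 0),
                    p_extra_meal = 0, p_late_meal = 0, p_early_meal = 0)
  co <- simulate_cohort(cfg)
  meals <- co$meal_truth[!is.na(co$meal_truth$time_category), ]
  feats <- meal_glucose_features(
    meals[, c("meal_id", "participant_id", "meal_timestamp")],
    co$glucose_traces
  )
  m <- dplyr::inner_join(feats, co$meal_truth[, c("meal_id", "intended_iauc")],
                         by = "meal_id")
  m <- m[!is.na(m$iauc_2h), ]
  expect_gt(nrow(m), 40)
  rel_err <- abs(m$iauc_2h - m$intended_iauc) /
    pmax(m$intended_iauc, 1) # guard the ratio for zero-iAUC meals
  expect_lt(max(rel_err), 0.05)
})

test_that("realized within-person variance tracks the configured ratio", {
  frac_within <- sapply(c(0.2, 1.4), function(wsd) {
    co <- simulate_cohort(sim_config(n_participants = 25, seed = 81,
                                     satiety_within_sd = wsd))
    d <- person_center(co$meal_truth, "satiety", grand_center = FALSE)
    var(d$satiety_w) / (var(d$satiety_w) + var(d$satiety_b))
  })
  expect_lt(frac_within[1], frac_within[2])
})

test_that("meal-level and stream-level generators share calibration", {
  tab <- simulate_meal_table(n_participants = 120, seed = 82)
  expect_equal(mean(tab$refined_grains), 0.68, tolerance = 0.05)
  expect_equal(mean(tab$sleep_h), 5.5, tolerance = 0.25)
  expect_equal(mean(tab$daily_lpa_h), 2.8, tolerance = 0.4)
  expect_true(all(tab$iauc_2h >= 0))
  expect_identical(tab, simulate_meal_table(n_participants = 120, seed = 82))
})
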