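small_tab <- function(seed = 51, n = 60, k = 10) {
  simulate_meal_table(n_participants = n, meals_per_participant = k,
                      seed = seed)
}

test_that("build_design assembles the documented term sets", {
  tab <- small_tab()
  full <- build_design(tab, mode = "full")
  expect_equal(sum(full$terms$level == "within"), 21)
  expect_equal(sum(full$terms$level == "between"), 21)
  expect_true("time_category" %in% full$terms$term)
  expect_true(all(c("age", "sex", "ethnicity", "education", "smoker",
                    "heavy_alcohol", "bmi", "preprandial_mean_2h") %in%
                    full$terms$term))
  basic <- build_design(tab, mode = "basic", exposure = "refined_grains")
  expect_equal(basic$terms$term[basic$terms$level == "within"],
               "refined_grains_w")
  expect_equal(basic$terms$term[basic$terms$level == "between"],
               "refined_grains_b")
  strat <- build_design(tab, mode = "full", drop_covariates = "sex")
  expect_false("sex" %in% strat$terms$term)
  nb <- build_design(tab, mode = "full", include_between = FALSE)
  expect_equal(sum(nb$terms$level == "between"), 0)
})

test_that("degenerate designs raise named errors", {
  tab <- small_tab()
  tab$vegetables <- 1L # constant flag -> zero within and constant between
  expect_error(build_design(tab, mode = "full"), "collinear")
  expect_error(build_design(tab[0, ], mode = "full"), "column|zero usable")
  expect_error(build_design(tab, mode = "basic"), "single canonical")
})

test_that("estimates are invariant to row order and duplication", {
  tab <- small_tab(n = 40, k = 8)
  f1 <- fit_iauc_model(tab, mode = "basic", exposure = "refined_grains")
  set.seed(52)
  f2 <- fit_iauc_model(tab[sample(nrow(tab)), ], mode = "basic",
                       exposure = "refined_grains")
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-6)
  # duplicating every row leaves estimates essentially unchanged (REML
  # reweights within/between information slightly, so only near-identity
  # holds for a mixed model)
  dup <- dplyr::bind_rows(tab, tab)
  f3 <- fit_iauc_model(dup, mode = "basic", exposure = "refined_grains")
  expect_lt(max(abs(f1$coefficients$beta - f3$coefficients$beta) /
                  f1$coefficients$se), 1)
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_iauc_model(small_tab(n = 40, k = 8), mode = "basic",
                        exposure = "sleep_h")
  td <- tidy(fit)
  expect_true(all(c("term", "level", "estimate", "std.error", "p.value")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$icc > 0 && gl$icc < 1)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("cluster bootstrap is reproducible and orders its bounds", {
  fit <- fit_iauc_model(small_tab(n = 35, k = 6), mode = "basic",
                        exposure = "refined_grains")
  ci1 <- bootstrap_ci(fit, B = 200, seed = 9)
  ci2 <- bootstrap_ci(fit, B = 200, seed = 9)
  expect_identical(ci1$ci_low, ci2$ci_low)
  expect_identical(ci1$ci_high, ci2$ci_high)
  expect_true(all(ci1$ci_low <= ci1$ci_high))
  expect_error(bootstrap_ci(fit, B = 50), ">= 200")
})

test_that("bootstrap intervals narrow as the cohort grows", {
  w <- sapply(c(30, 120), function(n) {
    fit <- fit_iauc_model(small_tab(seed = 53, n = n, k = 8),
                          mode = "basic", exposure = "refined_grains")
    ci <- bootstrap_ci(fit, B = 200, seed = 10)
    with(ci[ci$term == "refined_grains_w", ], ci_high - ci_low)
  })
  expect_lt(w[2], w[1] * 0.75) # ~1/sqrt(4) expected
})

test_that("interaction tests require a varying binary modifier", {
  tab <- small_tab(n = 50, k = 8)
  res <- interaction_test(tab, "sex",
                          exposures = c("refined_grains", "sleep_h"))
  expect_equal(sort(res$exposure), c("refined_grains", "sleep_h"))
  expect_true(all(res$flag %in% c("significant", "marginal", "ns")))
  tab$sex <- "female"
  expect_error(interaction_test(tab, "sex"), "constant")
})

test_that("stratified fits drop the stratifier and exclude between terms", {
  tab <- small_tab(n = 70, k = 8)
  st <- stratified_fit(tab, "sex",
                       exposures = c("refined_grains", "pp_mvpa_h", "sleep_h"))
  expect_setequal(unique(st$stratum), c("male", "female"))
  expect_false(any(grepl("^sex", st$term)))
  expect_false(any(st$level == "between"))
  # prediabetes strata match the diagnostic rule
  stp <- suppressWarnings(stratified_fit(tab, "prediabetes",
                                         exposures = c("refined_grains", "sleep_h")))
  n_rule <- length(unique(tab$participant_id[tab$fpg >= 5.6 | tab$hba1c >= 5.7]))
  pd <- unique(tab[, c("participant_id", "prediabetes")])
  expect_equal(sum(pd$prediabetes), n_rule)
})
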