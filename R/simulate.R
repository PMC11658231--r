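#' Ground truth for the synthetic cohort
#'
#' Bundles the simulation parameters that downstream parameter-recovery
#' tests are checked against: within- and between-person effects of every
#' canonical exposure on the 2-h postprandial glucose iAUC (mmol/l*min per
#' unit exposure), time-of-day effects relative to morning meals, the
#' model intercept, variance components, the baseline-glucose
#' distribution, and the shape of the postprandial response kernel.
#'
#' Default effect sizes are the package's reference effect set for
#' free-living Asian adults without diabetes (e.g. +46.2 mmol/l*min within
#' person for meals containing refined grains, -58.0 per hour of
#' postprandial moderate-to-vigorous activity, -2.7 per hour of
#' prior-night sleep, +54.4 for afternoon vs morning meals).
#'
#' @param within_effects Named numeric vector over [ppgr_exposures].
#' @param between_effects Same shape; defaults to `within_effects` except
#'   refined grains (51.7).
#' @param time_of_day_effects Named vector `c(afternoon = , evening = )`,
#'   iAUC units relative to morning.
#' @param intercept Expected iAUC (mmol/l*min) of a morning meal at zero
#'   exposures for an average person.
#' @param person_intercept_sd,residual_sd Between-person and
#'   meal-to-meal standard deviations of the iAUC (mmol/l*min).
#' @param baseline_glucose_mean,baseline_glucose_sd Person-level mean
#'   glucose distribution (mmol/l).
#' @param kernel_shape,kernel_scale Gamma-kernel parameters of the
#'   postprandial bump (minutes; peak at `(shape-1)*scale`, default 45
#'   min, support truncated at 120 min).
#' @return A list of class `ppgr_truth`.
#' @export
ground_truth <- function(
    within_effects = c(
      refined_grains = 46.2, whole_grains = 23.8, seafood = -8.6,
      chicken = -2.6, red_meat = -4.2, eggs = -5.2, dairy = -13.5,
      soy_food = -2.2, beans_or_nuts = -9.2, vegetables = 0.8,
      fruits = -7.1, deep_fried_food = 11.6, sweet_desserts = 4.0,
      sugary_beverages = -1.2, non_sugary_beverages = -9.5,
      satiety = 7.7, pp_lpa_h = -24.7, pp_mvpa_h = -58.0,
      daily_lpa_h = -7.5, daily_mvpa_h = 1.8, sleep_h = -2.7
    ),
    between_effects = NULL,
    time_of_day_effects = c(afternoon = 54.4, evening = 42.9),
    intercept = 96,
    person_intercept_sd = 30,
    residual_sd = 45,
    baseline_glucose_mean = 5.4,
    baseline_glucose_sd = 0.4,
    kernel_shape = 6,
    kernel_scale = 9) {
  if (is.null(between_effects)) {
    between_effects <- within_effects
    if ("refined_grains" %in% names(between_effects)) {
      between_effects[["refined_grains"]] <- 51.7
    }
  }
  bad <- setdiff(names(within_effects), ppgr_exposures)
  if (length(bad) > 0 || length(setdiff(names(between_effects), ppgr_exposures)) > 0) {
    abort(sprintf("effect name(s) not canonical: %s",
                  paste(unique(c(bad, setdiff(names(between_effects), ppgr_exposures))),
                        collapse = ", ")))
  }
  if (!all(names(time_of_day_effects) %in% c("afternoon", "evening"))) {
    abort("time_of_day_effects must be named 'afternoon' and 'evening'")
  }
  if (person_intercept_sd < 0 || residual_sd < 0) {
    abort("standard deviations must be non-negative")
  }
  # zero-fill unnamed exposures so lookups are total
  w <- setNames(numeric(length(ppgr_exposures)), ppgr_exposures)
  w[names(within_effects)] <- within_effects
  b <- setNames(numeric(length(ppgr_exposures)), ppgr_exposures)
  b[names(between_effects)] <- between_effects
  structure(list(
    within_effects = w, between_effects = b,
    time_of_day_effects = time_of_day_effects, intercept = intercept,
    person_intercept_sd = person_intercept_sd, residual_sd = residual_sd,
    baseline_glucose_mean = baseline_glucose_mean,
    baseline_glucose_sd = baseline_glucose_sd,
    kernel_shape = kernel_shape, kernel_scale = kernel_scale
  ), class = "ppgr_truth")
}

#' Simulation configuration
#'
#' Study-design parameters of the synthetic cohort: nine free-living days,
#' six EMA prompt windows per day, 15-min CGM sampling and 5-s
#' accelerometer epochs by default. The seed fully determines all outputs;
#' each participant draws from a stable sub-seeded stream so adding
#' participants does not perturb existing ones.
#'
#' @param n_participants Number of participants.
#' @param n_days Free-living days with meals (default 9). Streams start a
#'   day earlier so day-1 meals have full 24-h activity history.
#' @param seed Integer master seed.
#' @param ema_windows List of `c(start, end)` clock hours for the EMA
#'   prompts; must be ordered, non-overlapping and within 06:00-24:00.
#' @param cgm_interval_min CGM sampling interval (minutes).
#' @param epoch_seconds Accelerometer epoch length (seconds).
#' @param activity_block_min Length (minutes) of the constant-intensity
#'   blocks from which epochs are expanded; creates bout structure.
#' @param p_meals_per_day Probabilities of logging 1, 2 or 3 main meals on
#'   a day.
#' @param p_extra_meal Daily probability of an extra intake 1-2.4 h after
#'   a main meal (violates the 2.5-h spacing rule).
#' @param p_late_meal Daily probability of a late-evening intake
#'   (22:30-23:45), logged retrospectively the next morning.
#' @param p_early_meal Daily probability of a pre-06:00 intake (excluded
#'   by the clock-time rule).
#' @param grain_coupling Couple refined- and whole-grain flags through a
#'   shared "grains in this meal" draw, inducing the negative
#'   within-person correlation seen in real meal patterns.
#' @param missingness List with per-stream drop probabilities (`cgm`,
#'   `epochs`).
#' @param cgm_noise_sd CGM measurement noise (mmol/l).
#' @param circadian_amp Amplitude (mmol/l) of a 24-h sinusoidal term in
#'   the baseline glucose trace.
#' @param satiety_between_sd,satiety_within_sd Variance components of the
#'   satiety score (the dial used to test the within:between machinery).
#' @param activity Named list of the activity-process parameters: target
#'   marginal wake-time fractions spent in LPA and MVPA (`lpa_base`,
#'   `mvpa_base`; base logits are calibrated so the realized marginal
#'   means match these despite the logistic noise) and logit-scale
#'   person, day and hour standard deviations.
#' @param sleep_between_sd,sleep_within_sd,sleep_mean_h Sleep duration
#'   components (hours).
#' @return A list of class `ppgr_sim_config`.
#' @export
sim_config <- function(
    n_participants = 150, n_days = 9, seed = 1L,
    ema_windows = list(c(8, 9.5), c(10.5, 12), c(13, 14.5), c(15.5, 17),
                       c(18, 19.5), c(20.5, 21.5)),
    cgm_interval_min = 15, epoch_seconds = 5, activity_block_min = 1,
    p_meals_per_day = c(0.25, 0.5, 0.25),
    p_extra_meal = 0.08, p_late_meal = 0.05, p_early_meal = 0.01,
    grain_coupling = TRUE,
    missingness = list(cgm = 0.02, epochs = 0),
    cgm_noise_sd = 0.05, circadian_amp = 0.02,
    satiety_between_sd = 0.55, satiety_within_sd = 0.55,
    activity = list(
      lpa_base = 0.153, lpa_person_sd = 0.30, lpa_day_sd = 0.40, lpa_hour_sd = 0.8,
      mvpa_base = 0.0874, mvpa_person_sd = 0.45, mvpa_day_sd = 0.25, mvpa_hour_sd = 0.8
    ),
    sleep_mean_h = 5.5, sleep_between_sd = 0.9, sleep_within_sd = 1.1) {
  starts <- vapply(ema_windows, `[`, numeric(1), 1)
  ends <- vapply(ema_windows, `[`, numeric(1), 2)
  if (any(ends <= starts) || any(starts < 6) || any(ends > 24) ||
      is.unsorted(starts, strictly = TRUE) ||
      any(utils::head(ends, -1) > utils::tail(starts, -1))) {
    abort("configuration error: ema_windows must be ordered, non-overlapping, within 06:00-24:00")
  }
  if (n_participants < 1 || n_days < 1) {
    abort("configuration error: n_participants and n_days must be >= 1")
  }
  structure(as.list(environment()), class = "ppgr_sim_config")
}

#' Postprandial response kernel
#'
#' Gamma-shaped non-negative bump, zero at the meal time, peaking around
#' 45 min, truncated at the window end and normalised to unit area
#' (mmol/l*min scale), so a bump scaled by a target iAUC integrates back
#' to that target.
#'
#' @param u_min Minutes since the meal (vectorised).
#' @param shape,scale Gamma parameters (minutes).
#' @param support_min Truncation point (default 120).
#' @return Kernel values (per-minute density scale); 0 outside
#'   `(0, support_min]`.
#' @export
gamma_bump_kernel <- function(u_min, shape = 6, scale = 9,
                              support_min = 120) {
  norm <- stats::pgamma(support_min, shape = shape, scale = scale)
  out <- stats::dgamma(u_min, shape = shape, scale = scale) / norm
  out[u_min <= 0 | u_min > support_min] <- 0
  out
}

#' Intended iAUC of a simulated meal
#'
#' The simulation's linear model for the 2-h postprandial iAUC:
#' `max(0, intercept + sum(beta_w * (x - mu)) + sum(beta_b * mu) +
#' time-of-day effect + person intercept + Normal(0, residual_sd))`,
#' where `x` are the meal's exposure values and `mu` the person's latent
#' exposure means. The generated glucose bump is normalised to unit iAUC
#' and scaled by this value, so recomputing the iAUC from the trace
#' recovers it up to discretisation error.
#'
#' @param exposures Named numeric vector (subset of [ppgr_exposures]).
#' @param truth A [ground_truth()] object.
#' @param person_means Named numeric vector of latent person means
#'   (default all zero, in which case the within effects apply to the raw
#'   exposure values).
#' @param time_category One of the meal time-of-day levels.
#' @param person_intercept Person-level random intercept (mmol/l*min).
#' @param noise Residual draw; pass 0 for the deterministic predictor or
#'   leave `NULL` to draw `Normal(0, residual_sd)` from the current RNG
#'   stream.
#' @return iAUC in mmol/l*min (non-negative).
#' @export
intended_iauc <- function(exposures, truth,
                          person_means = NULL,
                          time_category = "morning_0600_1200",
                          person_intercept = 0, noise = NULL) {
  bad <- setdiff(names(exposures), ppgr_exposures)
  if (length(bad) > 0) {
    abort(sprintf("validation error: unknown exposure(s): %s",
                  paste(bad, collapse = ", ")))
  }
  x <- setNames(numeric(length(ppgr_exposures)), ppgr_exposures)
  x[names(exposures)] <- exposures
  mu <- setNames(numeric(length(ppgr_exposures)), ppgr_exposures)
  if (!is.null(person_means)) mu[names(person_means)] <- person_means
  tod <- c(morning_0600_1200 = 0,
           afternoon_1200_1800 = unname(truth$time_of_day_effects["afternoon"]),
           evening_1800_2400 = unname(truth$time_of_day_effects["evening"]))
  if (is.null(noise)) noise <- rnorm(1, 0, truth$residual_sd)
  lp <- truth$intercept +
    sum(truth$within_effects * (x - mu)) +
    sum(truth$between_effects * mu) +
    tod[[as.character(time_category)]] +
    person_intercept + noise
  max(0, lp)
}

# table-level linear predictor used by the generators (vectorised, no noise)
intended_lp <- function(expo, mu, time_category, truth) {
  x <- as.matrix(expo[, ppgr_exposures, drop = FALSE])
  m <- as.matrix(mu[, ppgr_exposures, drop = FALSE])
  tod <- c(morning_0600_1200 = 0,
           afternoon_1200_1800 = unname(truth$time_of_day_effects["afternoon"]),
           evening_1800_2400 = unname(truth$time_of_day_effects["evening"]))
  truth$intercept +
    drop((x - m) %*% truth$within_effects) +
    drop(m %*% truth$between_effects) +
    tod[as.character(time_category)]
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483587)
}

rclamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# E[plogis(base + sd*Z)], Z ~ N(0,1), by fixed-grid quadrature
logit_noise_mean <- function(base, sd) {
  if (sd <= 0) return(plogis(base))
  z <- seq(-5, 5, length.out = 61)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  vapply(base, function(b) sum(w * plogis(b + sd * z)), numeric(1))
}

# base logit whose noisy logistic mean hits `target`
logit_base_for <- function(target, sd) {
  vapply(target, function(p) {
    stats::uniroot(function(b) logit_noise_mean(b, sd) - p,
                   c(-10, 10), tol = 1e-8)$root
  }, numeric(1))
}

# observed meal-level food-group frequencies used as calibration targets
# (refined/whole grains are generated through the coupled grains draw)
ppgr_food_freq <- c(
  refined_grains = 0.68, whole_grains = 0.17, seafood = 0.21, chicken = 0.25,
  red_meat = 0.24, eggs = 0.22, dairy = 0.07, soy_food = 0.10,
  beans_or_nuts = 0.08, vegetables = 0.42, fruits = 0.13,
  deep_fried_food = 0.10, sweet_desserts = 0.07, sugary_beverages = 0.15,
  non_sugary_beverages = 0.30
)

# calibrated base logits shared by both generators; marginal means match the
# targets despite the logistic person/day/hour noise
sim_bases <- function(cfg) {
  act <- cfg$activity
  sd_l <- sqrt(act$lpa_person_sd^2 + act$lpa_day_sd^2 + act$lpa_hour_sd^2)
  sd_m <- sqrt(act$mvpa_person_sd^2 + act$mvpa_day_sd^2 + act$mvpa_hour_sd^2)
  list(
    food = logit_base_for(ppgr_food_freq, sd = 0.7),
    grain = logit_base_for(0.83, 0.7),   # P(any grains in meal)
    wref = logit_base_for(0.815, 1.0),   # refined share of grain meals
    lpa = logit_base_for(act$lpa_base, sd_l),
    mvpa = logit_base_for(act$mvpa_base, sd_m),
    lpa_mu_sd = sqrt(act$lpa_day_sd^2 + act$lpa_hour_sd^2),
    mvpa_mu_sd = sqrt(act$mvpa_day_sd^2 + act$mvpa_hour_sd^2)
  )
}

#' Generate a complete synthetic study cohort
#'
#' Produces the four record streams the real study collects (EMA meal
#' responses, CGM traces, 5-s ENMO epoch series, sleep windows) plus a
#' participant baseline table, with known ground truth: every generated
#' meal's intended iAUC follows the [intended_iauc()] linear model on the
#' *realized* activity/sleep exposures (computed from the generated
#' epochs with the same meal-anchored windows the analysis uses), and the
#' glucose trace carries a unit-iAUC bump scaled by that value on top of
#' a person baseline with a small circadian term and measurement noise.
#'
#' @param config A [sim_config()].
#' @param truth A [ground_truth()].
#' @return A list of class `ppgr_cohort`: `participants`,
#'   `ema_responses`, `glucose_traces`, `epoch_series`, `sleep_windows`,
#'   `meal_truth` (per generated meal: true timestamp, exposures,
#'   intended iAUC), `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), truth = ground_truth()) {
  if (!inherits(config, "ppgr_sim_config")) abort("config must come from sim_config()")
  if (!inherits(truth, "ppgr_truth")) abort("truth must come from ground_truth()")
  bases <- sim_bases(config)
  parts <- purrr::map(seq_len(config$n_participants), function(i) {
    sim_one_participant(sprintf("P%03d", i), derive_seed(config$seed, i),
                        config, truth, bases)
  })
  structure(list(
    participants = purrr::map_dfr(parts, "participant"),
    ema_responses = purrr::map_dfr(parts, "ema_responses"),
    glucose_traces = purrr::map_dfr(parts, "glucose"),
    epoch_series = purrr::map_dfr(parts, "epochs"),
    sleep_windows = purrr::map_dfr(parts, "sleep"),
    meal_truth = purrr::map_dfr(parts, "meal_truth"),
    truth = truth, config = config
  ), class = "ppgr_cohort")
}

sim_one_participant <- function(pid, pseed, config, truth, bases = sim_bases(config)) {
  set.seed(pseed)
  act <- config$activity
  date0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC") # first meal day
  span_start <- date0 - 86400
  span_end <- date0 + config$n_days * 86400 + 7200

  ## --- baseline characteristics -------------------------------------
  fpg <- rnorm(1, 5.0, 0.5)
  hba1c <- rnorm(1, 5.4, 0.3)
  participant <- tibble::tibble(
    participant_id = pid,
    age = round(runif(1, 21, 69)),
    sex = sample(c("male", "female"), 1, prob = c(0.36, 0.64)),
    ethnicity = sample(c("Chinese", "Malay", "Indian"), 1,
                       prob = c(0.75, 0.16, 0.09)),
    education = sample(c("secondary_or_below", "a_level", "university_or_above"),
                       1, prob = c(0.12, 0.29, 0.59)),
    smoker = runif(1) < 0.12,
    heavy_alcohol = runif(1) < 0.08,
    bmi = rclamp(rnorm(1, 24, 4.5), 16, 45),
    fpg = rclamp(fpg, 3.5, 6.9),
    hba1c = rclamp(hba1c, 4.3, 6.4)
  )
  participant$prediabetes <- participant$fpg >= 5.6 | participant$hba1c >= 5.7

  ## --- person-level latents ------------------------------------------
  b_iauc <- rnorm(1, 0, truth$person_intercept_sd)
  g_base <- rnorm(1, truth$baseline_glucose_mean, truth$baseline_glucose_sd)
  sleep_mu <- rclamp(rnorm(1, config$sleep_mean_h, config$sleep_between_sd), 3.5, 8.5)
  satiety_mu <- rclamp(rnorm(1, 3.8, config$satiety_between_sd), 1.5, 5.5)
  a_lpa <- rnorm(1, 0, act$lpa_person_sd)
  a_mvpa <- rnorm(1, 0, act$mvpa_person_sd)
  # latent food probabilities (between-person heterogeneity on the logit,
  # base logits calibrated so marginal frequencies match the targets)
  food_p <- plogis(bases$food + rnorm(length(bases$food), 0, 0.7))
  names(food_p) <- names(ppgr_food_freq)
  p_grain <- plogis(bases$grain + rnorm(1, 0, 0.7))  # any grains in a meal
  w_refined <- plogis(bases$wref + rnorm(1, 0, 1.0)) # refined share of grains
  p_both_grains <- 0.02

  ## --- sleep windows --------------------------------------------------
  n_nights <- config$n_days + 1 # nights before day 1 .. after last day
  onset <- date0 + ((seq_len(n_nights) - 1) * 86400) +
    (0.25 + rnorm(n_nights, 0, 0.6)) * 3600 # ~00:15 each day
  sleep_dur <- rclamp(sleep_mu + rnorm(n_nights, 0, config$sleep_within_sd), 3, 10)
  sleep <- tibble::tibble(
    participant_id = pid, onset = onset, wake = onset + sleep_dur * 3600
  )
  # enforce non-overlap (can only occur with extreme draws)
  keep <- c(TRUE, sleep$onset[-1] > sleep$wake[-n_nights])
  sleep <- sleep[keep, , drop = FALSE]

  ## --- meal schedule --------------------------------------------------
  # wake clock hour per meal day (so breakfasts start after waking)
  wake_hour <- rep(6, config$n_days)
  for (d in seq_len(config$n_days)) {
    day_start <- as.numeric(date0) + (d - 1) * 86400
    w <- as.numeric(sleep$wake)
    cand <- w[w > day_start & w < day_start + 12 * 3600]
    if (length(cand) > 0) wake_hour[d] <- (max(cand) - day_start) / 3600
  }
  cat_hours <- list(
    morning_0600_1200 = c(6.5, 9.0),
    afternoon_1200_1800 = c(12.0, 14.0),
    evening_1800_2400 = c(18.0, 21.0)
  )
  meal_day <- integer(0); meal_hour <- numeric(0); meal_kind <- character(0)
  for (d in seq_len(config$n_days)) {
    n_m <- sample(1:3, 1, prob = config$p_meals_per_day)
    cats <- sample(names(cat_hours), n_m, prob = c(0.28, 0.36, 0.36))
    for (cc in cats) {
      h <- runif(1, cat_hours[[cc]][1], cat_hours[[cc]][2])
      if (cc == "morning_0600_1200") {
        h <- min(max(h, wake_hour[d] + 0.3), 11.5)
      }
      meal_day <- c(meal_day, d)
      meal_hour <- c(meal_hour, h)
      meal_kind <- c(meal_kind, "main")
    }
    if (runif(1) < config$p_extra_meal && length(cats) > 0) {
      anchor <- meal_hour[length(meal_hour) - sample(seq_along(cats), 1) + 1]
      h <- anchor + runif(1, 1, 2.4)
      if (h < 23.9) {
        meal_day <- c(meal_day, d); meal_hour <- c(meal_hour, h)
        meal_kind <- c(meal_kind, "extra")
      }
    }
    if (runif(1) < config$p_late_meal) {
      meal_day <- c(meal_day, d)
      meal_hour <- c(meal_hour, runif(1, 22.5, 23.75))
      meal_kind <- c(meal_kind, "late")
    }
    if (runif(1) < config$p_early_meal) {
      meal_day <- c(meal_day, d)
      meal_hour <- c(meal_hour, runif(1, 5.0, 5.9))
      meal_kind <- c(meal_kind, "early")
    }
  }
  meal_hour <- floor(meal_hour * 60) / 60 # reported to the minute
  meal_t <- date0 + (meal_day - 1) * 86400 + meal_hour * 3600
  o <- order(meal_t)
  meal_day <- meal_day[o]; meal_hour <- meal_hour[o]
  meal_kind <- meal_kind[o]; meal_t <- meal_t[o]
  n_meals <- length(meal_t)

  ## --- meal composition & satiety -------------------------------------
  flags <- matrix(0L, n_meals, length(ppgr_food_groups),
                  dimnames = list(NULL, ppgr_food_groups))
  for (f in ppgr_food_groups) {
    if (config$grain_coupling && f %in% c("refined_grains", "whole_grains")) next
    flags[, f] <- as.integer(runif(n_meals) < food_p[[f]])
  }
  if (config$grain_coupling) {
    has_grain <- runif(n_meals) < p_grain
    u <- runif(n_meals)
    both <- has_grain & u < p_both_grains
    refined_only <- has_grain & !both & (u < p_both_grains + (1 - p_both_grains) * w_refined)
    whole_only <- has_grain & !both & !refined_only
    flags[, "refined_grains"] <- as.integer(refined_only | both)
    flags[, "whole_grains"] <- as.integer(whole_only | both)
  } else {
    flags[, "refined_grains"] <- as.integer(runif(n_meals) < food_p[["refined_grains"]])
    flags[, "whole_grains"] <- as.integer(runif(n_meals) < food_p[["whole_grains"]])
  }
  satiety <- as.integer(round(rclamp(
    satiety_mu + rnorm(n_meals, 0, config$satiety_within_sd), 1, 6)))

  ## --- activity process (constant-band blocks expanded to epochs) -----
  block_s <- config$activity_block_min * 60
  n_blocks <- ceiling(as.numeric(span_end - span_start, units = "secs") / block_s)
  bt <- as.numeric(span_start) + (seq_len(n_blocks) - 1) * block_s
  hr_idx <- floor((bt - bt[1]) / 3600) + 1
  day_idx <- floor((bt - bt[1]) / 86400) + 1
  eta_l_h <- rnorm(max(hr_idx), 0, act$lpa_hour_sd)
  eta_m_h <- rnorm(max(hr_idx), 0, act$mvpa_hour_sd)
  eta_l_d <- rnorm(max(day_idx), 0, act$lpa_day_sd)
  eta_m_d <- rnorm(max(day_idx), 0, act$mvpa_day_sd)
  p_m <- plogis(bases$mvpa + a_mvpa + eta_m_d[day_idx] + eta_m_h[hr_idx])
  p_l <- plogis(bases$lpa + a_lpa + eta_l_d[day_idx] + eta_l_h[hr_idx])
  p_l <- pmin(p_l, 1 - p_m - 1e-6)
  asleep <- rep(FALSE, n_blocks)
  for (k in seq_len(nrow(sleep))) {
    asleep[bt >= as.numeric(sleep$onset[k]) & bt < as.numeric(sleep$wake[k])] <- TRUE
  }
  u <- runif(n_blocks)
  band <- ifelse(asleep, 0L, ifelse(u < p_m, 2L, ifelse(u < p_m + p_l, 1L, 0L)))
  enmo_block <- numeric(n_blocks)
  n0 <- sum(band == 0L); n1 <- sum(band == 1L); n2 <- sum(band == 2L)
  enmo_block[band == 0L] <- runif(n0, 0, 35)
  enmo_block[band == 1L] <- runif(n1, 45, 95)
  if (n2 > 0) { # 3% of MVPA blocks vigorous (>= 400 mg)
    vig <- runif(n2) < 0.03
    e2 <- numeric(n2)
    e2[!vig] <- runif(sum(!vig), 105, 390)
    e2[vig] <- runif(sum(vig), 400, 600)
    enmo_block[band == 2L] <- e2
  }
  per_block <- block_s / config$epoch_seconds
  ep_t <- as.numeric(span_start) + (seq_len(n_blocks * per_block) - 1) * config$epoch_seconds
  ep_enmo <- rep(enmo_block, each = per_block)
  if (config$missingness$epochs > 0) {
    keep_ep <- runif(length(ep_t)) >= config$missingness$epochs
    ep_t <- ep_t[keep_ep]; ep_enmo <- ep_enmo[keep_ep]
  }
  epochs <- tibble::tibble(
    participant_id = pid,
    timestamp = as.POSIXct(ep_t, tz = "UTC", origin = "1970-01-01"),
    enmo_mg = ep_enmo
  )

  ## --- realized exposures and intended iAUC ---------------------------
  meal_tbl <- tibble::tibble(
    meal_id = sprintf("%s_m%02d", pid, seq_len(n_meals)),
    participant_id = pid, meal_timestamp = meal_t
  )
  act_feat <- meal_activity_features(meal_tbl, epochs, sleep,
                                     epoch_seconds = config$epoch_seconds)
  expo <- tibble::as_tibble(flags) |>
    dplyr::mutate(
      satiety = satiety,
      pp_lpa_h = act_feat$pp_lpa_h, pp_mvpa_h = act_feat$pp_mvpa_h,
      daily_lpa_h = act_feat$daily_lpa_h, daily_mvpa_h = act_feat$daily_mvpa_h,
      sleep_h = dplyr::coalesce(act_feat$sleep_h, sleep_mu)
    )
  # latent person means of each exposure (used by the truth linear model)
  wake_h <- 24 - sleep_mu
  mu_lpa <- logit_noise_mean(bases$lpa + a_lpa, bases$lpa_mu_sd)
  mu_mvpa <- logit_noise_mean(bases$mvpa + a_mvpa, bases$mvpa_mu_sd)
  mu_vec <- c(
    food_p[ppgr_food_groups],
    satiety = satiety_mu,
    pp_lpa_h = 2 * mu_lpa,
    pp_mvpa_h = 2 * mu_mvpa,
    daily_lpa_h = wake_h * mu_lpa,
    daily_mvpa_h = wake_h * mu_mvpa,
    sleep_h = sleep_mu
  )
  if (config$grain_coupling) {
    mu_vec[["refined_grains"]] <- p_grain * (p_both_grains + (1 - p_both_grains) * w_refined)
    mu_vec[["whole_grains"]] <- p_grain * (p_both_grains + (1 - p_both_grains) * (1 - w_refined))
  }
  mu <- tibble::as_tibble(as.list(mu_vec))[rep(1, n_meals), ]
  time_cat <- meal_time_category(meal_t)
  time_cat_lp <- as.character(time_cat)
  time_cat_lp[is.na(time_cat_lp)] <- "morning_0600_1200" # pre-06:00 intakes
  lp <- intended_lp(expo, mu, time_cat_lp, truth) + b_iauc +
    rnorm(n_meals, 0, truth$residual_sd)
  iauc_true <- pmax(0, lp)

  ## --- CGM trace -------------------------------------------------------
  cg_t <- seq(as.numeric(span_start), as.numeric(span_end),
              by = config$cgm_interval_min * 60)
  gl <- g_base +
    config$circadian_amp * sin(2 * pi * ((cg_t / 3600) %% 24 - 10) / 24) +
    rnorm(length(cg_t), 0, config$cgm_noise_sd)
  for (j in seq_len(n_meals)) {
    t0 <- as.numeric(meal_t[j])
    in_win <- which(cg_t > t0 & cg_t <= t0 + 7200)
    if (length(in_win) > 0) {
      gl[in_win] <- gl[in_win] + iauc_true[j] *
        gamma_bump_kernel((cg_t[in_win] - t0) / 60,
                          truth$kernel_shape, truth$kernel_scale)
    }
  }
  if (config$missingness$cgm > 0) {
    keep_cg <- runif(length(cg_t)) >= config$missingness$cgm
    cg_t <- cg_t[keep_cg]; gl <- gl[keep_cg]
  }
  glucose <- tibble::tibble(
    participant_id = pid,
    timestamp = as.POSIXct(cg_t, tz = "UTC", origin = "1970-01-01"),
    glucose_mmol_l = gl
  )

  ## --- EMA responses ----------------------------------------------------
  win_start <- vapply(config$ema_windows, `[`, numeric(1), 1)
  win_end <- vapply(config$ema_windows, `[`, numeric(1), 2)
  resp_day <- meal_day
  resp_win <- integer(n_meals)
  occasion <- character(n_meals)
  for (j in seq_len(n_meals)) {
    h <- meal_hour[j]
    w <- which(win_end >= h + 0.2)
    if (length(w) == 0) { # after the last prompt: reported next morning
      resp_day[j] <- meal_day[j] + 1
      resp_win[j] <- 1L
      occasion[j] <- "after_last_ema_yesterday"
    } else {
      resp_win[j] <- w[1]
      occasion[j] <- if (w[1] == 1L) "since_waking" else "since_last_prompt"
    }
  }
  resp_lo <- ifelse(resp_day > meal_day, win_start[resp_win],
                    pmax(win_start[resp_win], meal_hour + 0.1))
  resp_h <- runif(n_meals, resp_lo, win_end[resp_win])
  ema <- tibble::as_tibble(flags) |>
    dplyr::mutate(
      participant_id = pid,
      response_timestamp = date0 + (resp_day - 1) * 86400 + resp_h * 3600,
      occasion = occasion,
      reported_clock_time = sprintf("%02d:%02d", floor(meal_hour),
                                    round((meal_hour %% 1) * 60)),
      satiety = satiety
    ) |>
    dplyr::select("participant_id", "response_timestamp", "occasion",
                  "reported_clock_time", dplyr::all_of(ppgr_food_groups),
                  "satiety")

  list(
    participant = participant,
    ema_responses = ema,
    glucose = glucose,
    epochs = epochs,
    sleep = sleep,
    meal_truth = dplyr::bind_cols(
      meal_tbl[, c("meal_id", "participant_id", "meal_timestamp")],
      tibble::tibble(kind = meal_kind, time_category = time_cat,
                     intended_iauc = iauc_true,
                     person_intercept = b_iauc),
      expo
    )
  )
}

#' Simulate a meal-level analysis table directly
#'
#' A light-weight twin of [simulate_cohort()] for model-calibration
#' experiments: draws the meal-level exposures from the same person-level
#' variance structure (latent person means plus occasion deviations, the
#' same grain coupling) and the outcome from the same linear model, but
#' skips stream synthesis (no CGM/epoch traces). The returned table is
#' analysis-ready (it mimics the output of the feature-extraction
#' stages).
#'
#' @param truth A [ground_truth()].
#' @param n_participants,meals_per_participant Cohort dimensions.
#' @param seed Integer seed.
#' @param grain_coupling As in [sim_config()].
#' @return A tibble with `participant_id`, `meal_id`, `time_category`,
#'   the exposures, the baseline covariates, `preprandial_mean_2h` and
#'   `iauc_2h`; the generating truth is attached as attribute `"truth"`.
#' @export
simulate_meal_table <- function(truth = ground_truth(), n_participants = 150,
                                meals_per_participant = 18, seed = 1L,
                                grain_coupling = TRUE) {
  cfg <- sim_config(n_participants = n_participants, seed = seed,
                    grain_coupling = grain_coupling)
  act <- cfg$activity
  bases <- sim_bases(cfg)
  rows <- purrr::map_dfr(seq_len(n_participants), function(i) {
    set.seed(derive_seed(seed, i))
    pid <- sprintf("P%03d", i)
    n <- meals_per_participant
    b_iauc <- rnorm(1, 0, truth$person_intercept_sd)
    g_base <- rnorm(1, truth$baseline_glucose_mean, truth$baseline_glucose_sd)
    sleep_mu <- rclamp(rnorm(1, cfg$sleep_mean_h, cfg$sleep_between_sd), 3.5, 8.5)
    satiety_mu <- rclamp(rnorm(1, 3.8, cfg$satiety_between_sd), 1.5, 5.5)
    a_lpa <- rnorm(1, 0, act$lpa_person_sd)
    a_mvpa <- rnorm(1, 0, act$mvpa_person_sd)
    food_p <- plogis(bases$food + rnorm(length(bases$food), 0, 0.7))
    names(food_p) <- names(ppgr_food_freq)
    p_grain <- plogis(bases$grain + rnorm(1, 0, 0.7))
    w_refined <- plogis(bases$wref + rnorm(1, 0, 1.0))
    p_both <- 0.02
    flags <- matrix(0L, n, length(ppgr_food_groups),
                    dimnames = list(NULL, ppgr_food_groups))
    for (f in ppgr_food_groups) {
      if (grain_coupling && f %in% c("refined_grains", "whole_grains")) next
      flags[, f] <- as.integer(runif(n) < food_p[[f]])
    }
    if (grain_coupling) {
      has_grain <- runif(n) < p_grain
      u <- runif(n)
      both <- has_grain & u < p_both
      r_only <- has_grain & !both & (u < p_both + (1 - p_both) * w_refined)
      w_only <- has_grain & !both & !r_only
      flags[, "refined_grains"] <- as.integer(r_only | both)
      flags[, "whole_grains"] <- as.integer(w_only | both)
      mu_r <- p_grain * (p_both + (1 - p_both) * w_refined)
      mu_w <- p_grain * (p_both + (1 - p_both) * (1 - w_refined))
    } else {
      flags[, "refined_grains"] <- as.integer(runif(n) < food_p[["refined_grains"]])
      flags[, "whole_grains"] <- as.integer(runif(n) < food_p[["whole_grains"]])
      mu_r <- food_p[["refined_grains"]]; mu_w <- food_p[["whole_grains"]]
    }
    wake_h <- 24 - sleep_mu
    mu_lpa <- logit_noise_mean(bases$lpa + a_lpa, bases$lpa_mu_sd)
    mu_mvpa <- logit_noise_mean(bases$mvpa + a_mvpa, bases$mvpa_mu_sd)
    mu_vec <- c(
      food_p[ppgr_food_groups],
      satiety = satiety_mu,
      pp_lpa_h = 2 * mu_lpa,
      pp_mvpa_h = 2 * mu_mvpa,
      daily_lpa_h = wake_h * mu_lpa,
      daily_mvpa_h = wake_h * mu_mvpa,
      sleep_h = sleep_mu
    )
    mu_vec[["refined_grains"]] <- mu_r
    mu_vec[["whole_grains"]] <- mu_w
    expo <- tibble::as_tibble(flags) |>
      dplyr::mutate(
        satiety = as.integer(round(rclamp(
          satiety_mu + rnorm(n, 0, cfg$satiety_within_sd), 1, 6))),
        pp_lpa_h = rclamp(mu_vec[["pp_lpa_h"]] + rnorm(n, 0, 0.12), 0, 2),
        pp_mvpa_h = rclamp(mu_vec[["pp_mvpa_h"]] + rnorm(n, 0, 0.10), 0, 2),
        daily_lpa_h = rclamp(mu_vec[["daily_lpa_h"]] + rnorm(n, 0, 1.0), 0, 16),
        daily_mvpa_h = rclamp(mu_vec[["daily_mvpa_h"]] + rnorm(n, 0, 0.45), 0, 12),
        sleep_h = rclamp(sleep_mu + rnorm(n, 0, cfg$sleep_within_sd), 3, 10)
      )
    time_category <- sample(ppgr_time_levels, n, replace = TRUE,
                            prob = c(0.30, 0.35, 0.35))
    mu <- tibble::as_tibble(as.list(mu_vec))[rep(1, n), ]
    y <- pmax(0, intended_lp(expo, mu, time_category, truth) + b_iauc +
                rnorm(n, 0, truth$residual_sd))
    fpg <- rclamp(rnorm(1, 5.0, 0.5), 3.5, 6.9)
    hba1c <- rclamp(rnorm(1, 5.4, 0.3), 4.3, 6.4)
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = pid,
        meal_id = sprintf("%s_m%02d", pid, seq_len(n)),
        time_category = factor(time_category, levels = ppgr_time_levels),
        age = round(runif(1, 21, 69)),
        sex = sample(c("male", "female"), 1, prob = c(0.36, 0.64)),
        ethnicity = sample(c("Chinese", "Malay", "Indian"), 1,
                           prob = c(0.75, 0.16, 0.09)),
        education = sample(c("secondary_or_below", "a_level",
                             "university_or_above"), 1,
                           prob = c(0.12, 0.29, 0.59)),
        smoker = runif(1) < 0.12,
        heavy_alcohol = runif(1) < 0.08,
        bmi = rclamp(rnorm(1, 24, 4.5), 16, 45),
        fpg = fpg, hba1c = hba1c,
        prediabetes = fpg >= 5.6 | hba1c >= 5.7,
        preprandial_mean_2h = g_base + rnorm(n, 0, 0.15),
        iauc_2h = y
      ),
      expo
    )
  })
  attr(rows, "truth") <- truth
  rows
}
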