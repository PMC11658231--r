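#' Reconstruct meal timestamps from EMA responses
#'
#' Each EMA survey response reports a meal clock time in "HH:MM" which is
#' combined with the automatically recorded response date. For meals
#' reported on the first survey of the day as eaten *after the last survey
#' yesterday*, an evening clock time refers to the previous calendar day;
#' a small-hours clock time (after midnight, before sleep) refers to the
#' response date itself. All other occasions use the response date.
#'
#' @param responses A data frame of EMA responses: `participant_id`,
#'   `response_timestamp` (POSIXct), `occasion` (one of
#'   `"since_last_prompt"`, `"after_last_ema_yesterday"`,
#'   `"since_waking"`), `reported_clock_time` ("HH:MM"), the 15 food-group
#'   flag columns ([ppgr_food_groups]) and `satiety` (integer 1-6).
#' @return A tibble of meal records: `meal_id`, `participant_id`,
#'   `meal_timestamp`, `time_category`, the food flags, and `satiety`.
#'   Rows with unparseable clock times are dropped with a warning, as are
#'   duplicate reports of the same meal (identical participant and
#'   timestamp; the first is kept).
#' @details The "evening vs after-midnight" split for
#'   `after_last_ema_yesterday` is taken at 12:00: reported clock times at
#'   or after noon map to the day before the response, earlier ones to the
#'   response date. The last survey window ends at 21:30, so meals logged
#'   retrospectively the next morning fall in 21:30-06:00 and the split is
#'   unambiguous in practice.
#' @export
resolve_meal_timestamps <- function(responses) {
  stopifnot_cols(
    responses,
    c("participant_id", "response_timestamp", "occasion",
      "reported_clock_time", "satiety"),
    "responses"
  )
  responses <- tibble::as_tibble(responses)
  m <- regmatches(
    responses$reported_clock_time,
    regexec("^([0-9]{1,2}):([0-9]{2})$", responses$reported_clock_time)
  )
  hh <- vapply(m, function(x) if (length(x) == 3) as.numeric(x[2]) else NA_real_,
               numeric(1))
  mm <- vapply(m, function(x) if (length(x) == 3) as.numeric(x[3]) else NA_real_,
               numeric(1))
  bad <- is.na(hh) | is.na(mm) | hh > 23 | mm > 59
  if (any(bad)) {
    warn(sprintf(
      "dropping %d EMA response(s) with unparseable meal clock time (e.g. %s)",
      sum(bad), responses$reported_clock_time[which(bad)[1]]
    ))
  }
  ok <- responses[!bad, , drop = FALSE]
  hh <- hh[!bad]
  mm <- mm[!bad]
  resp_t <- as_utc(ok$response_timestamp)
  resp_day <- as.POSIXct(trunc(resp_t, "days"))
  shift_day <- ok$occasion == "after_last_ema_yesterday" & hh >= 12
  meal_t <- resp_day - ifelse(shift_day, 86400, 0) + hh * 3600 + mm * 60

  out <- dplyr::mutate(
    ok,
    meal_timestamp = meal_t,
    time_category = meal_time_category(meal_t),
    .keep = "all"
  )
  dup <- duplicated(out[c("participant_id", "meal_timestamp")])
  if (any(dup)) {
    warn(sprintf("dropping %d duplicate meal report(s) (same participant and timestamp)",
                 sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  out <- dplyr::arrange(out, .data$participant_id, .data$meal_timestamp)
  keep <- intersect(ppgr_food_groups, names(out))
  dplyr::select(
    dplyr::mutate(out, meal_id = sprintf("meal_%05d", dplyr::row_number())),
    "meal_id", "participant_id", "meal_timestamp", "time_category",
    dplyr::all_of(keep), "satiety"
  )
}

#' Time-of-day category of a meal
#'
#' Half-open intervals on the meal clock time: morning `[06:00, 12:00)`,
#' afternoon `[12:00, 18:00)`, evening `[18:00, 24:00)`. Meals before
#' 06:00 get `NA` (they are excluded by qualification).
#'
#' @param meal_timestamp POSIXct vector.
#' @return Factor with levels morning_0600_1200, afternoon_1200_1800,
#'   evening_1800_2400.
#' @export
meal_time_category <- function(meal_timestamp) {
  t <- as_utc(meal_timestamp)
  mins <- as.numeric(t - as.POSIXct(trunc(t, "days")), units = "mins")
  factor(
    dplyr::case_when(
      mins >= 360 & mins < 720 ~ "morning_0600_1200",
      mins >= 720 & mins < 1080 ~ "afternoon_1200_1800",
      mins >= 1080 & mins < 1440 ~ "evening_1800_2400",
      TRUE ~ NA_character_
    ),
    levels = ppgr_time_levels
  )
}

#' Apply the meal-level inclusion rules
#'
#' A meal qualifies for analysis when (1) time-matched CGM coverage exists
#' around it, (2) no other reported food intake occurred within 2.5 h
#' before it, and (3) it was consumed between 06:00 and 24:00. The rules
#' are applied independently and every failure reason is reported. Rule
#' (2) uses *all reported* meals, qualified or not.
#'
#' @param meals Meal records (`meal_id`, `participant_id`,
#'   `meal_timestamp`), e.g. from [resolve_meal_timestamps()].
#' @param cgm CGM readings (`participant_id`, `timestamp`,
#'   `glucose_mmol_l`).
#' @param spacing_h Prior-intake exclusion window in hours (default 2.5);
#'   the window is `[t - spacing_h, t)`.
#' @param coverage_min_frac Minimum fraction of expected postprandial
#'   readings required in `(t, t+2h]` (default 0.8, i.e. 7 of 8 at 15-min
#'   spacing).
#' @param cgm_interval_min Nominal CGM sampling interval (minutes).
#' @param pre_min,post_min Pre- and postprandial coverage windows
#'   (minutes).
#' @return A qualification audit tibble: `meal_id`, `participant_id`,
#'   `qualified`, the three reason flags (`no_cgm_coverage`,
#'   `prior_intake_within_2p5h`, `outside_0600_2400`) and
#'   `failure_reasons` (semicolon-separated string, empty when
#'   qualified).
#' @export
qualify_meals <- function(meals, cgm, spacing_h = 2.5,
                          coverage_min_frac = 0.8, cgm_interval_min = 15,
                          pre_min = 120, post_min = 120) {
  stopifnot_cols(meals, c("meal_id", "participant_id", "meal_timestamp"), "meals")
  stopifnot_cols(cgm, c("participant_id", "timestamp", "glucose_mmol_l"), "cgm")
  meals <- dplyr::arrange(tibble::as_tibble(meals),
                          .data$participant_id, .data$meal_timestamp)
  mt <- as.numeric(as_utc(meals$meal_timestamp))
  pid <- as.character(meals$participant_id)

  # (3) clock-time rule, [06:00, 24:00)
  mins <- {
    t <- as_utc(meals$meal_timestamp)
    as.numeric(t - as.POSIXct(trunc(t, "days")), units = "mins")
  }
  outside <- mins < 360 # < 06:00; midnight wrap is its own day's [0, 360)

  # (2) prior intake in [t - spacing, t), any reported meal; with meals
  # sorted within participant this reduces to the gap to the previous one
  prev_gap <- ifelse(pid == dplyr::lag(pid, default = ""),
                     mt - dplyr::lag(mt, default = -Inf), Inf)
  prior <- prev_gap <= spacing_h * 3600 & prev_gap > 0 # closed at t-2.5h, open at t

  # (1) CGM coverage
  n_req <- ceiling(coverage_min_frac * post_min / cgm_interval_min)
  traces <- split(as.numeric(as_utc(cgm$timestamp)), as.character(cgm$participant_id))
  no_cov <- vapply(seq_along(mt), function(i) {
    tt <- traces[[pid[i]]]
    if (is.null(tt) || length(tt) == 0) return(TRUE)
    pre_ok <- any(tt >= mt[i] - pre_min * 60 & tt <= mt[i])
    n_post <- sum(tt > mt[i] & tt <= mt[i] + post_min * 60)
    span_ok <- max(tt) >= mt[i] + post_min * 60 - cgm_interval_min * 60
    !(pre_ok && n_post >= n_req && span_ok)
  }, logical(1))

  reasons <- cbind(no_cgm_coverage = no_cov,
                   prior_intake_within_2p5h = prior,
                   outside_0600_2400 = outside)
  tibble::tibble(
    meal_id = meals$meal_id,
    participant_id = meals$participant_id,
    qualified = !rowSums(reasons) > 0,
    no_cgm_coverage = no_cov,
    prior_intake_within_2p5h = prior,
    outside_0600_2400 = outside,
    failure_reasons = apply(reasons, 1, function(r)
      paste(colnames(reasons)[r], collapse = ";"))
  )
}

#' Apply the participant-level inclusion rule
#'
#' Participants with fewer than `min_meals` qualifying meals are excluded
#' from the analysis.
#'
#' @param qualification Output of [qualify_meals()] (or any table with
#'   `participant_id` and `qualified`).
#' @param min_meals Minimum number of qualified meals (default 3,
#'   inclusive).
#' @return Tibble: `participant_id`, `n_qualified`, `retained`.
#' @export
filter_participants <- function(qualification, min_meals = 3) {
  stopifnot_cols(qualification, c("participant_id", "qualified"), "qualification")
  qualification |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_qualified = sum(.data$qualified), .groups = "drop") |>
    dplyr::mutate(retained = .data$n_qualified >= min_meals)
}
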