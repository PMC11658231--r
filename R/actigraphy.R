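#' Classify ENMO epochs into intensity bands
#'
#' Applies the wrist-accelerometer ENMO cut-points: epochs below 40
#' milligravity are inactive, 40 to <100 mg are light-intensity physical
#' activity (LPA), and >=100 mg are moderate-to-vigorous physical activity
#' (MVPA). Epochs at >=400 mg are additionally flagged vigorous (a subset
#' of MVPA). Boundaries are inclusive at the lower edge of each band.
#'
#' @param epochs A data frame with an `enmo_mg` column (plus any other
#'   columns, which are preserved).
#' @param lpa_mg,mvpa_mg,vigorous_mg ENMO thresholds in milligravity.
#' @return `epochs` with columns `band` (factor inactive/lpa/mvpa) and
#'   `vigorous` (logical) appended.
#' @export
classify_epochs <- function(epochs, lpa_mg = 40, mvpa_mg = 100,
                            vigorous_mg = 400) {
  stopifnot_cols(epochs, "enmo_mg", "epochs")
  dplyr::mutate(
    tibble::as_tibble(epochs),
    band = enmo_band(.data$enmo_mg, lpa_mg, mvpa_mg),
    vigorous = .data$enmo_mg >= vigorous_mg
  )
}

#' @rdname classify_epochs
#' @param enmo_mg Numeric ENMO values (milligravity), finite and >= 0.
#' @return For `enmo_band()`, a factor with levels inactive, lpa, mvpa.
#' @export
enmo_band <- function(enmo_mg, lpa_mg = 40, mvpa_mg = 100) {
  if (any(!is.finite(enmo_mg)) || any(enmo_mg < 0)) {
    abort("ENMO values must be finite and non-negative")
  }
  factor(
    dplyr::case_when(
      enmo_mg >= mvpa_mg ~ "mvpa",
      enmo_mg >= lpa_mg ~ "lpa",
      TRUE ~ "inactive"
    ),
    levels = c("inactive", "lpa", "mvpa")
  )
}

#' Hours of an intensity band inside a time window
#'
#' Total duration of one intensity band inside a window: the count of
#' epochs of that band whose timestamps fall in the window, times the epoch
#' length, converted to hours. No bout-length requirement is applied.
#'
#' @param epochs One participant's epochs: `timestamp`, `enmo_mg` (or a
#'   pre-computed `band` column from [classify_epochs()]).
#' @param from,to Window bounds (POSIXct).
#' @param band `"inactive"`, `"lpa"` or `"mvpa"`.
#' @param epoch_seconds Epoch length (default 5 s).
#' @param bounds Interval convention: `"(]"` (default, used for the
#'   postprandial window), `"[)"` (daily window), `"[]"` or `"()"`.
#' @return Hours (numeric scalar); 0 for an empty window.
#' @export
duration_in_window <- function(epochs, from, to,
                               band = c("lpa", "mvpa", "inactive"),
                               epoch_seconds = 5, bounds = "(]") {
  band <- match.arg(band)
  stopifnot_cols(epochs, "timestamp", "epochs")
  if (!bounds %in% c("(]", "[)", "[]", "()")) {
    abort('bounds must be one of "(]", "[)", "[]", "()"')
  }
  b <- if ("band" %in% names(epochs)) as.character(epochs$band) else
    as.character(enmo_band(epochs$enmo_mg))
  tt <- as.numeric(as_utc(epochs$timestamp))
  a <- as.numeric(as_utc(from))
  z <- as.numeric(as_utc(to))
  if (z < a) abort("window must satisfy to >= from")
  lo <- if (substr(bounds, 1, 1) == "[") tt >= a else tt > a
  hi <- if (substr(bounds, 2, 2) == "]") tt <= z else tt < z
  sum(lo & hi & b == band) * epoch_seconds / 3600
}

#' Sleep duration the night before a meal
#'
#' Duration (hours) of the most recent sleep window whose wake time is at
#' or before the meal time and within 24 h of it; `NA` when no such window
#' exists. When several windows qualify (e.g. a nap after the main sleep),
#' the one with the latest wake wins.
#'
#' @param sleep One participant's sleep windows: `onset`, `wake`
#'   (POSIXct), non-overlapping.
#' @param meal_time POSIXct meal timestamp (scalar).
#' @return Hours of sleep, or `NA_real_`.
#' @export
sleep_before <- function(sleep, meal_time) {
  stopifnot_cols(sleep, c("onset", "wake"), "sleep")
  onset <- as.numeric(as_utc(sleep$onset))
  wake <- as.numeric(as_utc(sleep$wake))
  if (any(wake <= onset)) abort("sleep windows must satisfy wake > onset")
  o <- order(onset)
  if (any(onset[o][-1] < wake[o][-length(o)])) {
    abort("sleep windows overlap within participant")
  }
  t0 <- as.numeric(as_utc(meal_time))[1]
  ok <- wake <= t0 & wake > t0 - 86400
  if (!any(ok)) return(NA_real_)
  i <- which(ok)[which.max(wake[ok])]
  (wake[i] - onset[i]) / 3600
}

#' Meal-anchored activity features for one participant
#'
#' Applies [duration_in_window()] to the 2-h postprandial window
#' `(t, t+2h]` and the 24-h pre-meal window `[t-24h, t)` for both LPA and
#' MVPA. Windows extending beyond the epoch series span yield `NA`.
#'
#' @inheritParams duration_in_window
#' @param meal_time POSIXct meal timestamp (scalar).
#' @param min_wear_frac Minimum fraction of a window covered by epochs
#'   (wear time) for its features to be computed; below it the features
#'   are `NA` rather than imputed.
#' @return Named list with `pp_lpa_h`, `pp_mvpa_h`, `daily_lpa_h`,
#'   `daily_mvpa_h`.
#' @export
meal_activity <- function(epochs, meal_time, epoch_seconds = 5,
                          min_wear_frac = 0.9) {
  t0 <- as_utc(meal_time)[1]
  tt <- as.numeric(as_utc(epochs$timestamp))
  span_lo <- min(tt) - epoch_seconds
  span_hi <- max(tt) + epoch_seconds
  t0n <- as.numeric(t0)
  wear_pp <- sum(tt > t0n & tt <= t0n + 7200) * epoch_seconds / 7200
  wear_dd <- sum(tt >= t0n - 86400 & tt < t0n) * epoch_seconds / 86400
  pp_ok <- t0n >= span_lo && t0n + 7200 <= span_hi && wear_pp >= min_wear_frac
  dd_ok <- t0n - 86400 >= span_lo && t0n <= span_hi && wear_dd >= min_wear_frac
  list(
    pp_lpa_h = if (pp_ok) duration_in_window(epochs, t0, t0 + 7200, "lpa",
                                             epoch_seconds, "(]") else NA_real_,
    pp_mvpa_h = if (pp_ok) duration_in_window(epochs, t0, t0 + 7200, "mvpa",
                                              epoch_seconds, "(]") else NA_real_,
    daily_lpa_h = if (dd_ok) duration_in_window(epochs, t0 - 86400, t0, "lpa",
                                                epoch_seconds, "[)") else NA_real_,
    daily_mvpa_h = if (dd_ok) duration_in_window(epochs, t0 - 86400, t0, "mvpa",
                                                 epoch_seconds, "[)") else NA_real_
  )
}

#' Per-meal activity and sleep features for a whole cohort
#'
#' Vectorised equivalent of [meal_activity()] + [sleep_before()] over a
#' meal table: for each meal, hours of LPA and MVPA in the 2-h postprandial
#' window `(t, t+2h]`, hours of LPA and MVPA in the 24-h pre-meal window
#' `[t-24h, t)`, and the prior night's sleep duration. Uses cumulative
#' band counts per participant so cost is near-linear in the number of
#' epochs.
#'
#' @param meals Data frame with `meal_id`, `participant_id`,
#'   `meal_timestamp`.
#' @param epochs Data frame with `participant_id`, `timestamp`, `enmo_mg`.
#' @param sleep Data frame with `participant_id`, `onset`, `wake`.
#' @inheritParams duration_in_window
#' @inheritParams classify_epochs
#' @return `meals` with `pp_lpa_h`, `pp_mvpa_h`, `daily_lpa_h`,
#'   `daily_mvpa_h`, `sleep_h` appended (`NA` where a window is not covered
#'   by the epoch series, wear falls below `min_wear_frac`, or no
#'   qualifying sleep window exists).
#' @export
meal_activity_features <- function(meals, epochs, sleep, epoch_seconds = 5,
                                   lpa_mg = 40, mvpa_mg = 100,
                                   min_wear_frac = 0.9) {
  stopifnot_cols(meals, c("meal_id", "participant_id", "meal_timestamp"), "meals")
  stopifnot_cols(epochs, c("participant_id", "timestamp", "enmo_mg"), "epochs")
  stopifnot_cols(sleep, c("participant_id", "onset", "wake"), "sleep")

  ep_by <- split(seq_len(nrow(epochs)), epochs$participant_id)
  sl_by <- split(sleep, sleep$participant_id)
  ep_tt <- as.numeric(as_utc(epochs$timestamp))
  ep_enmo <- epochs$enmo_mg
  if (any(!is.finite(ep_enmo)) || any(ep_enmo < 0)) {
    abort("ENMO values must be finite and non-negative")
  }

  meals <- tibble::as_tibble(meals)
  mt <- as.numeric(as_utc(meals$meal_timestamp))
  n <- nrow(meals)
  pp_lpa <- pp_mvpa <- dd_lpa <- dd_mvpa <- sl_h <- rep(NA_real_, n)

  for (pid in unique(as.character(meals$participant_id))) {
    rows <- which(as.character(meals$participant_id) == pid)
    idx <- ep_by[[pid]]
    if (!is.null(idx) && length(idx) > 0) {
      tt <- ep_tt[idx]
      o <- order(tt)
      tt <- tt[o]
      en <- ep_enmo[idx][o]
      is_lpa <- en >= lpa_mg & en < mvpa_mg
      is_mvpa <- en >= mvpa_mg
      cl <- c(0, cumsum(is_lpa))
      cm <- c(0, cumsum(is_mvpa))
      n_le <- function(x) findInterval(x, tt)                  # tt <= x
      n_lt <- function(x) findInterval(x, tt, left.open = TRUE) # tt <  x
      span_lo <- tt[1] - epoch_seconds
      span_hi <- tt[length(tt)] + epoch_seconds
      t0 <- mt[rows]
      # wear fraction from epoch presence inside each window
      wear_pp <- (n_le(t0 + 7200) - n_le(t0)) * epoch_seconds / 7200
      wear_dd <- (n_lt(t0) - n_lt(t0 - 86400)) * epoch_seconds / 86400
      pp_ok <- t0 >= span_lo & t0 + 7200 <= span_hi & wear_pp >= min_wear_frac
      dd_ok <- t0 - 86400 >= span_lo & t0 <= span_hi & wear_dd >= min_wear_frac
      # postprandial (t, t+2h]: epochs with t < tt <= t+2h
      a <- n_le(t0) + 1L
      b <- n_le(t0 + 7200) + 1L
      pp_lpa[rows] <- ifelse(pp_ok, (cl[b] - cl[a]) * epoch_seconds / 3600, NA)
      pp_mvpa[rows] <- ifelse(pp_ok, (cm[b] - cm[a]) * epoch_seconds / 3600, NA)
      # daily [t-24h, t): epochs with t-24h <= tt < t
      a2 <- n_lt(t0 - 86400) + 1L
      b2 <- n_lt(t0) + 1L
      dd_lpa[rows] <- ifelse(dd_ok, (cl[b2] - cl[a2]) * epoch_seconds / 3600, NA)
      dd_mvpa[rows] <- ifelse(dd_ok, (cm[b2] - cm[a2]) * epoch_seconds / 3600, NA)
    }
    sw <- sl_by[[pid]]
    if (!is.null(sw) && nrow(sw) > 0) {
      sl_h[rows] <- vapply(
        rows,
        function(r) sleep_before(sw, meals$meal_timestamp[r]), numeric(1)
      )
    }
  }
  dplyr::mutate(meals,
    pp_lpa_h = pp_lpa, pp_mvpa_h = pp_mvpa,
    daily_lpa_h = dd_lpa, daily_mvpa_h = dd_mvpa, sleep_h = sl_h
  )
}
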