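#' Interpolate glucose at an arbitrary time
#'
#' Continuous glucose monitors sample on a nominal 15-min grid, but
#' self-reported meal times rarely coincide with a reading. `glucose_at()`
#' returns the linearly interpolated glucose value at `at`, using the two
#' readings bracketing it. If `at` coincides with a reading, that reading's
#' value is returned exactly.
#'
#' @param readings A data frame of one participant's CGM readings with
#'   columns `timestamp` (POSIXct) and `glucose_mmol_l`, strictly increasing
#'   in time.
#' @param at POSIXct time(s) at which to evaluate the trace.
#' @param max_gap_min Maximum allowed gap (minutes) between the bracketing
#'   readings; queries falling in a larger gap are coverage errors.
#' @return Numeric vector of glucose values (mmol/l).
#' @examples
#' tr <- tibble::tibble(
#'   timestamp = as.POSIXct("2023-01-02 08:00", tz = "UTC") + c(0, 900),
#'   glucose_mmol_l = c(5, 6)
#' )
#' glucose_at(tr, as.POSIXct("2023-01-02 08:07:30", tz = "UTC"))
#' @export
glucose_at <- function(readings, at, max_gap_min = 45) {
  stopifnot_cols(readings, c("timestamp", "glucose_mmol_l"), "readings")
  tt <- as.numeric(as_utc(readings$timestamp))
  interp_glucose(tt, readings$glucose_mmol_l, as.numeric(as_utc(at)),
                 max_gap_s = max_gap_min * 60)
}

# numeric-core interpolation; times in seconds
interp_glucose <- function(tt, gg, at, max_gap_s) {
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("CGM timestamps must be strictly increasing within participant")
  }
  out <- numeric(length(at))
  for (k in seq_along(at)) {
    a <- at[k]
    if (length(tt) == 0 || a < tt[1] || a > tt[length(tt)]) {
      abort(sprintf(
        "coverage error: query time outside trace span [%s, %s]",
        format(as.POSIXct(tt[1], tz = "UTC", origin = "1970-01-01")),
        format(as.POSIXct(tt[length(tt)], tz = "UTC", origin = "1970-01-01"))
      ))
    }
    i <- findInterval(a, tt)
    if (tt[i] == a) {
      out[k] <- gg[i]
    } else {
      if (tt[i + 1] - tt[i] > max_gap_s) {
        abort(sprintf(
          "coverage error: gap of %.1f min around query exceeds %.1f min",
          (tt[i + 1] - tt[i]) / 60, max_gap_s / 60
        ))
      }
      w <- (a - tt[i]) / (tt[i + 1] - tt[i])
      out[k] <- (1 - w) * gg[i] + w * gg[i + 1]
    }
  }
  out
}

#' Two-hour postprandial incremental area under the curve
#'
#' Computes the incremental area under the glucose curve over the window
#' after a meal, relative to the glucose level at the meal time itself
#' (trapezoidal rule on the piecewise-linear trace). In `positive_only`
#' mode (the conventional iAUC) only segments above baseline contribute,
#' with trapezoids split exactly at baseline crossings; in `net` mode
#' signed increments are integrated.
#'
#' @inheritParams glucose_at
#' @param meal_time POSIXct meal timestamp (scalar).
#' @param mode `"positive_only"` (default) or `"net"`.
#' @param window_min Postprandial window length in minutes (default 120).
#' @param baseline `"interpolated"` (glucose interpolated at the meal time,
#'   default) or `"locf"` (last reading at or before the meal time).
#' @return iAUC in mmol/l*min.
#' @details The curve is the baseline point at the meal time, the readings
#'   in `(meal_time, meal_time + window]`, and, when a reading exists
#'   beyond the window within the interpolation gap tolerance, an
#'   interpolated endpoint at exactly `meal_time + window`; otherwise the
#'   curve is truncated at the last in-window reading.
#' @export
iauc_2h <- function(readings, meal_time,
                    mode = c("positive_only", "net"),
                    window_min = 120,
                    baseline = c("interpolated", "locf"),
                    max_gap_min = 45) {
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  stopifnot_cols(readings, c("timestamp", "glucose_mmol_l"), "readings")
  tt <- as.numeric(as_utc(readings$timestamp))
  iauc_core(tt, readings$glucose_mmol_l, as.numeric(as_utc(meal_time))[1],
            mode, window_min * 60, baseline, max_gap_min * 60)
}

iauc_core <- function(tt, gg, t0, mode, window_s, baseline, max_gap_s) {
  if (baseline == "interpolated") {
    base <- interp_glucose(tt, gg, t0, max_gap_s)
  } else {
    i <- findInterval(t0, tt)
    if (i < 1) abort("coverage error: no reading at or before the meal time")
    base <- gg[i]
  }
  t_end <- t0 + window_s
  inside <- which(tt > t0 & tt <= t_end)
  if (length(inside) == 0) {
    abort(sprintf("coverage error: no readings in the %d-min postprandial window",
                  round(window_s / 60)))
  }
  x <- c(t0, tt[inside])
  y <- c(base, gg[inside])
  last_in <- inside[length(inside)]
  if (tt[last_in] < t_end) {
    # interpolate the window endpoint when a bracketing reading exists
    if (last_in < length(tt) && (tt[last_in + 1] - tt[last_in]) <= max_gap_s) {
      x <- c(x, t_end)
      y <- c(y, interp_glucose(tt, gg, t_end, max_gap_s))
    } # else: truncate at the last in-window reading
  }
  d <- y - base
  dt <- diff(x) / 60 # minutes
  d1 <- d[-length(d)]
  d2 <- d[-1]
  if (mode == "net") {
    return(sum((d1 + d2) / 2 * dt))
  }
  # positive-only: split each trapezoid at its baseline crossing
  area <- numeric(length(dt))
  both_pos <- d1 >= 0 & d2 >= 0
  area[both_pos] <- ((d1 + d2) / 2 * dt)[both_pos]
  cross <- (d1 > 0) != (d2 > 0) & (d1 != 0 | d2 != 0) & !both_pos
  if (any(cross)) {
    frac <- d1[cross] / (d1[cross] - d2[cross]) # position of the crossing
    up <- d1[cross] > 0
    pos_len <- ifelse(up, frac, 1 - frac) * dt[cross]
    pos_h <- ifelse(up, d1[cross], d2[cross])
    area[cross] <- pos_h * pos_len / 2
  }
  sum(area)
}

#' Pre-prandial mean glucose
#'
#' Arithmetic mean of the CGM readings in the closed 2-h window before a
#' meal, used both as a covariate and for reporting.
#'
#' @inheritParams iauc_2h
#' @param window_min Pre-prandial window length in minutes (default 120).
#' @return Mean glucose (mmol/l).
#' @export
preprandial_mean <- function(readings, meal_time, window_min = 120) {
  stopifnot_cols(readings, c("timestamp", "glucose_mmol_l"), "readings")
  tt <- as.numeric(as_utc(readings$timestamp))
  t0 <- as.numeric(as_utc(meal_time))[1]
  sel <- tt >= t0 - window_min * 60 & tt <= t0
  if (!any(sel)) {
    abort("coverage error: no readings in the pre-prandial window")
  }
  mean(readings$glucose_mmol_l[sel])
}

#' Whole-wear glucose summaries per participant
#'
#' Mean glucose and coefficient of variation (100 x sd/mean) over each
#' participant's full wear period.
#'
#' @param cgm A data frame of CGM readings with columns `participant_id`,
#'   `timestamp`, `glucose_mmol_l`.
#' @return A tibble with one row per participant: `participant_id`,
#'   `mean_glucose`, `cv_percent`, `n_readings`.
#' @export
participant_glycemia <- function(cgm) {
  stopifnot_cols(cgm, c("participant_id", "timestamp", "glucose_mmol_l"), "cgm")
  out <- cgm |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      mean_glucose = mean(.data$glucose_mmol_l),
      cv_percent = 100 * sd(.data$glucose_mmol_l) / mean(.data$glucose_mmol_l),
      n_readings = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_readings < 2)) {
    abort("participant_glycemia() needs at least 2 readings per participant")
  }
  out
}

#' Per-meal glucose features
#'
#' Computes, for every meal, the 2-h postprandial iAUC, the 2-h
#' pre-prandial mean, the baseline (meal-time) glucose, and the number of
#' postprandial readings used.
#'
#' @param meals A data frame with `meal_id`, `participant_id`,
#'   `meal_timestamp`.
#' @param cgm CGM readings (`participant_id`, `timestamp`,
#'   `glucose_mmol_l`).
#' @inheritParams iauc_2h
#' @return `meals` with columns `iauc_2h`, `preprandial_mean_2h`,
#'   `baseline_glucose`, `postprandial_n_readings` appended. Meals whose
#'   windows are not covered get `NA` features (they are expected to be
#'   removed by qualification beforehand).
#' @export
meal_glucose_features <- function(meals, cgm,
                                  mode = c("positive_only", "net"),
                                  window_min = 120,
                                  baseline = c("interpolated", "locf"),
                                  max_gap_min = 45) {
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  stopifnot_cols(meals, c("meal_id", "participant_id", "meal_timestamp"), "meals")
  stopifnot_cols(cgm, c("participant_id", "timestamp", "glucose_mmol_l"), "cgm")
  traces <- split(cgm, cgm$participant_id)
  feat <- purrr::pmap(
    list(meals$participant_id, as.numeric(as_utc(meals$meal_timestamp))),
    function(pid, t0) {
      tr <- traces[[as.character(pid)]]
      if (is.null(tr)) {
        return(list(iauc_2h = NA_real_, preprandial_mean_2h = NA_real_,
                    baseline_glucose = NA_real_, postprandial_n_readings = 0L))
      }
      tt <- as.numeric(as_utc(tr$timestamp))
      gg <- tr$glucose_mmol_l
      n_post <- sum(tt > t0 & tt <= t0 + window_min * 60)
      res <- try(list(
        iauc_2h = iauc_core(tt, gg, t0, mode, window_min * 60, baseline,
                            max_gap_min * 60),
        preprandial_mean_2h = {
          sel <- tt >= t0 - window_min * 60 & tt <= t0
          if (any(sel)) mean(gg[sel]) else abort("no pre-prandial readings")
        },
        baseline_glucose = if (baseline == "interpolated") {
          interp_glucose(tt, gg, t0, max_gap_min * 60)
        } else gg[findInterval(t0, tt)],
        postprandial_n_readings = n_post
      ), silent = TRUE)
      if (inherits(res, "try-error")) {
        list(iauc_2h = NA_real_, preprandial_mean_2h = NA_real_,
             baseline_glucose = NA_real_, postprandial_n_readings = n_post)
      } else res
    }
  )
  dplyr::bind_cols(
    tibble::as_tibble(meals),
    purrr::map_dfr(feat, tibble::as_tibble)
  )
}
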