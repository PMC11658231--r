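# shared fixture builders (all data generated in code; no files)

utc <- function(x) as.POSIXct(x, tz = "UTC")
T0 <- utc("2023-01-02 08:00:00")

# one participant's CGM trace from values on a regular grid
make_trace <- function(values, start = T0, by_min = 15, pid = "P1") {
  tibble::tibble(
    participant_id = pid,
    timestamp = start + (seq_along(values) - 1) * by_min * 60,
    glucose_mmol_l = values
  )
}

# a long flat trace covering [start - pre_h, start + post_h]
flat_trace <- function(level = 5, start = T0, pre_h = 4, post_h = 16,
                       by_min = 15, pid = "P1") {
  t <- seq(start - pre_h * 3600, start + post_h * 3600, by = by_min * 60)
  tibble::tibble(participant_id = pid, timestamp = t,
                 glucose_mmol_l = rep(level, length(t)))
}

# epoch series with constant enmo, 5-s spacing
make_epochs <- function(enmo, start = T0, pid = "P1", epoch_s = 5) {
  tibble::tibble(
    participant_id = pid,
    timestamp = start + (seq_along(enmo) - 1) * epoch_s,
    enmo_mg = enmo
  )
}

# random piecewise-linear trace around a 5 mmol/l baseline with a reading
# exactly at the meal time (so the baseline is unambiguous)
random_trace <- function(rng_n = 12, start = T0) {
  vals <- 5 + c(0, cumsum(runif(rng_n - 1, -0.8, 1.0)))
  vals <- pmax(vals, 0.5)
  make_trace(vals, start = start - 900)
}

# independent fine-grid iAUC oracle: resample the piecewise-linear curve on
# a 1-s grid and integrate increments above baseline (or signed)
fine_grid_iauc <- function(trace, meal_time, mode = "positive_only",
                           window_min = 120) {
  tt <- as.numeric(trace$timestamp)
  t0 <- as.numeric(meal_time)
  base <- approx(tt, trace$glucose_mmol_l, t0)$y
  grid <- seq(t0, t0 + window_min * 60, by = 1)
  g <- approx(tt, trace$glucose_mmol_l, grid)$y
  d <- g - base
  if (mode == "positive_only") {
    # refine the grid with the baseline-crossing roots of the sampled
    # curve so the clipped integrand is piecewise linear on the grid
    ch <- which(d[-1] * d[-length(d)] < 0)
    if (length(ch) > 0) {
      root <- grid[ch] + d[ch] / (d[ch] - d[ch + 1])
      grid <- sort(c(grid, root))
      g <- approx(tt, trace$glucose_mmol_l, grid)$y
      d <- g - base
    }
    d <- pmax(d, 0)
  }
  sum(diff(grid) * (head(d, -1) + tail(d, -1)) / 2) / 60 # seconds -> minutes
}

# meal-level EMA response row
ema_row <- function(pid, resp, occ, clock, satiety = 4, flags = NULL) {
  out <- tibble::tibble(
    participant_id = pid, response_timestamp = utc(resp),
    occasion = occ, reported_clock_time = clock, satiety = satiety
  )
  fl <- setNames(as.list(rep(0L, length(ppgr_food_groups))), ppgr_food_groups)
  if (!is.null(flags)) fl[flags] <- 1L
  dplyr::bind_cols(out, tibble::as_tibble(fl))
}
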