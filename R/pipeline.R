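#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one object. All
#' thresholds exposed by the individual stages appear here with their
#' defaults; all randomness funnels through the single `seed`.
#'
#' @param simulate `NULL`, or a list passed to [sim_config()] (plus an
#'   optional `truth` element from [ground_truth()]) to generate the
#'   input streams.
#' @param inputs `NULL`, or a named list of CSV paths: `ema`, `cgm`,
#'   `epochs`, `sleep`, `participants`. Exactly one of `simulate` /
#'   `inputs` must be given.
#' @param filters Meal/participant inclusion rules: `spacing_h` (2.5),
#'   `coverage_min_frac` (0.8), `cgm_interval_min` (15), `min_meals` (3).
#' @param iauc iAUC options: `mode` ("positive_only" or "net"),
#'   `baseline` ("interpolated" or "locf"), `max_gap_min` (45).
#' @param activity ENMO thresholds, epoch length and wear rule:
#'   `lpa_mg` (40), `mvpa_mg` (100), `epoch_seconds` (5),
#'   `min_wear_frac` (0.9).
#' @param models Association-model options: `fit` (fit any models at
#'   all, TRUE), `bootstrap` (TRUE), `B` (200), `basic` (fit
#'   per-exposure basic models, TRUE), `strata` (character subset of
#'   "sex", "prediabetes"), `interactions` (same).
#' @param icc Variance-decomposition options: `run` (TRUE), `measures`
#'   (NULL = canonical exposures + iauc_2h).
#' @param seed Master seed (also the simulation seed unless `simulate`
#'   carries its own).
#' @param out_dir Directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return A list of class `ppgr_config`.
#' @export
ppgr_config <- function(simulate = list(), inputs = NULL,
                        filters = list(), iauc = list(), activity = list(),
                        models = list(), icc = list(),
                        seed = 1L, out_dir = NULL) {
  defaults <- list(
    filters = list(spacing_h = 2.5, coverage_min_frac = 0.8,
                   cgm_interval_min = 15, min_meals = 3),
    iauc = list(mode = "positive_only", baseline = "interpolated",
                max_gap_min = 45),
    activity = list(lpa_mg = 40, mvpa_mg = 100, epoch_seconds = 5,
                    min_wear_frac = 0.9),
    models = list(fit = TRUE, bootstrap = TRUE, B = 200, basic = TRUE,
                  strata = character(0), interactions = character(0)),
    icc = list(run = TRUE, measures = NULL)
  )
  merge_in <- function(def, user) utils::modifyList(def, as.list(user))
  if (!is.null(simulate) && !is.null(inputs)) {
    abort("configuration error: give either `simulate` or `inputs`, not both")
  }
  if (is.null(simulate) && is.null(inputs)) {
    abort("configuration error: one of `simulate` or `inputs` is required")
  }
  if (!is.null(inputs)) {
    need <- c("ema", "cgm", "epochs", "sleep", "participants")
    missing_keys <- setdiff(need, names(inputs))
    if (length(missing_keys) > 0) {
      abort(sprintf("configuration error: inputs lacks %s",
                    paste(missing_keys, collapse = ", ")))
    }
    gone <- !vapply(unlist(inputs[need]), file.exists, logical(1))
    if (any(gone)) {
      abort(sprintf("pre-flight error: missing input file(s): %s",
                    paste(unlist(inputs[need])[gone], collapse = ", ")))
    }
  }
  structure(list(
    simulate = simulate, inputs = inputs,
    filters = merge_in(defaults$filters, filters),
    iauc = merge_in(defaults$iauc, iauc),
    activity = merge_in(defaults$activity, activity),
    models = merge_in(defaults$models, models),
    icc = merge_in(defaults$icc, icc),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "ppgr_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, meal-timestamp resolution,
#' qualification, feature extraction, within/between decomposition,
#' association models and reporting from a single configuration.
#' Deterministic for a given configuration and seed.
#'
#' @param config A [ppgr_config()], or the path to a YAML file whose keys
#'   mirror its arguments.
#' @return A list of class `ppgr_run`: `events` (the analysis table),
#'   `audit` (qualification audit), `participants`, `retention`,
#'   `vardecomp`, `fit_full` (`ppgr_fit`), `ci_full`, `basic_estimates`,
#'   `stratified`, `interactions`, `manifest`. When `out_dir` is set the
#'   tables are also written as CSV, the manifest as JSON and a plain-text
#'   log with per-stage counts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- do.call(ppgr_config, raw)
  }
  if (!inherits(config, "ppgr_config")) {
    abort("config must be a ppgr_config or a YAML path")
  }
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  ## inputs ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    truth <- sim_args$truth %||% ground_truth()
    sim_args$truth <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- simulate_cohort(do.call(sim_config, sim_args), truth)
    ema <- cohort$ema_responses
    cgm <- cohort$glucose_traces
    epochs <- cohort$epoch_series
    sleep <- cohort$sleep_windows
    participants <- cohort$participants
    say("simulated cohort: %d participants, seed %d",
        nrow(participants), sim_args$seed)
  } else {
    read_csv_ <- function(p) tibble::as_tibble(utils::read.csv(p))
    ema <- read_csv_(config$inputs$ema)
    cgm <- read_csv_(config$inputs$cgm)
    epochs <- read_csv_(config$inputs$epochs)
    sleep <- read_csv_(config$inputs$sleep)
    participants <- read_csv_(config$inputs$participants)
    for (nm in c("response_timestamp")) ema[[nm]] <- as_utc(ema[[nm]])
    cgm$timestamp <- as_utc(cgm$timestamp)
    epochs$timestamp <- as_utc(epochs$timestamp)
    sleep$onset <- as_utc(sleep$onset)
    sleep$wake <- as_utc(sleep$wake)
    cohort <- NULL
  }

  ## meal events --------------------------------------------------------
  meals <- resolve_meal_timestamps(ema)
  say("EMA responses: %d; parsed meal records: %d", nrow(ema), nrow(meals))
  audit <- qualify_meals(
    meals, cgm,
    spacing_h = config$filters$spacing_h,
    coverage_min_frac = config$filters$coverage_min_frac,
    cgm_interval_min = config$filters$cgm_interval_min
  )
  retention <- filter_participants(audit, min_meals = config$filters$min_meals)
  keep_ids <- retention$participant_id[retention$retained]
  qualified <- meals |>
    dplyr::semi_join(dplyr::filter(audit, .data$qualified), by = "meal_id") |>
    dplyr::filter(.data$participant_id %in% keep_ids)
  say("qualified meals: %d of %d; retained participants: %d of %d",
      sum(audit$qualified), nrow(audit), length(keep_ids), nrow(retention))

  ## features ------------------------------------------------------------
  feats <- qualified |>
    meal_glucose_features(
      cgm, mode = config$iauc$mode, baseline = config$iauc$baseline,
      max_gap_min = config$iauc$max_gap_min
    ) |>
    meal_activity_features(
      epochs, sleep,
      epoch_seconds = config$activity$epoch_seconds,
      lpa_mg = config$activity$lpa_mg, mvpa_mg = config$activity$mvpa_mg,
      min_wear_frac = config$activity$min_wear_frac
    )
  events <- feats |>
    dplyr::inner_join(participants, by = "participant_id") |>
    person_center()
  say("analysis events: %d rows", nrow(events))

  ## decomposition --------------------------------------------------------
  vardecomp <- NULL
  if (isTRUE(config$icc$run)) {
    vardecomp <- variance_decomposition(events, measures = config$icc$measures)
    say("variance decomposition: %d measures", nrow(vardecomp))
  }

  ## models ----------------------------------------------------------------
  fit_full <- NULL
  ci_full <- NULL
  if (isTRUE(config$models$fit)) {
  fit_full <- fit_iauc_model(events, mode = "full")
  say("full model: %d fixed effects, converged=%s",
      nrow(fit_full$coefficients), fit_full$converged)
  if (isTRUE(config$models$bootstrap)) {
    ci_full <- bootstrap_ci(fit_full, B = config$models$B, seed = config$seed)
    say("bootstrap: B=%d, failed=%d", attr(ci_full, "B"),
        attr(ci_full, "n_failed"))
  }
  } # end models$fit
  basic_estimates <- NULL
  if (isTRUE(config$models$fit) && isTRUE(config$models$basic)) {
    expos <- intersect(ppgr_exposures, names(events))
    basic_estimates <- purrr::map_dfr(expos, function(e) {
      fb <- fit_iauc_model(events, mode = "basic", exposure = e)
      dplyr::mutate(
        dplyr::filter(fb$coefficients, .data$level %in% c("within", "between")),
        exposure = e, .before = 1
      )
    })
    say("basic models: %d exposures", length(expos))
  }
  stratified <- purrr::map(
    setNames(config$models$strata, config$models$strata),
    function(sv) stratified_fit(events, sv)
  )
  interactions <- purrr::map(
    setNames(config$models$interactions, config$models$interactions),
    function(sv) interaction_test(events, sv)
  )

  ## manifest ---------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("ppgr")),
    seed = config$seed,
    counts = list(
      participants_input = nrow(participants),
      ema_responses = nrow(ema),
      meals_parsed = nrow(meals),
      meals_qualified = sum(audit$qualified),
      meals_failed_no_cgm_coverage = sum(audit$no_cgm_coverage),
      meals_failed_prior_intake = sum(audit$prior_intake_within_2p5h),
      meals_failed_clock_window = sum(audit$outside_0600_2400),
      participants_retained = length(keep_ids),
      analysis_events = nrow(events),
      model_rows = if (!is.null(fit_full)) nrow(fit_full$design$data) else 0L,
      model_rows_dropped = if (!is.null(fit_full)) fit_full$design$n_dropped else 0L
    ),
    models = if (!is.null(fit_full)) list(
      bootstrap_B = if (isTRUE(config$models$bootstrap)) config$models$B else 0L,
      bootstrap_failed = if (!is.null(ci_full)) attr(ci_full, "n_failed") else NA_integer_,
      full_converged = fit_full$converged,
      full_singular = fit_full$singular
    ) else list()
  )

  run <- structure(list(
    events = events, audit = audit, participants = participants,
    retention = retention, vardecomp = vardecomp,
    fit_full = fit_full, ci_full = ci_full,
    basic_estimates = basic_estimates,
    stratified = stratified, interactions = interactions,
    manifest = manifest, cohort = cohort, log = log_lines
  ), class = "ppgr_run")

  if (!is.null(config$out_dir)) {
    write_run(run, config$out_dir)
  }
  run
}

fmt_iso <- function(x) format(as_utc(x), "%Y-%m-%dT%H:%M:%SZ")

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(function(x) inherits(x, "POSIXct")), fmt_iso
    ))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(run$events, "events.csv")
  wcsv(run$audit, "qualification_audit.csv")
  wcsv(run$retention, "participant_retention.csv")
  if (!is.null(run$vardecomp)) wcsv(run$vardecomp, "variance_decomposition.csv")
  if (!is.null(run$fit_full)) {
    full_tbl <- if (!is.null(run$ci_full)) {
      tibble::as_tibble(run$ci_full)
    } else {
      run$fit_full$coefficients
    }
    wcsv(full_tbl, "full_model_estimates.csv")
  }
  if (!is.null(run$basic_estimates)) wcsv(run$basic_estimates, "basic_model_estimates.csv")
  for (nm in names(run$stratified)) {
    wcsv(run$stratified[[nm]], sprintf("stratified_%s.csv", nm))
  }
  for (nm in names(run$interactions)) {
    wcsv(run$interactions[[nm]], sprintf("interactions_%s.csv", nm))
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(run)
}

#' @export
print.ppgr_run <- function(x, ...) {
  cat("<ppgr_run>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a simulated cohort's streams to CSV
#'
#' Serialises the four record streams plus the participant table with
#' ISO-8601 UTC timestamps, the configuration as YAML and the ground
#' truth as JSON, so a cohort can be re-ingested through the
#' `inputs` branch of [run_pipeline()].
#'
#' @param cohort A `ppgr_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "ppgr_cohort")) abort("cohort must be a ppgr_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  streams <- list(
    participants = cohort$participants,
    ema = cohort$ema_responses,
    cgm = cohort$glucose_traces,
    epochs = cohort$epoch_series,
    sleep = cohort$sleep_windows,
    meal_truth = cohort$meal_truth
  )
  paths <- vapply(names(streams), function(nm) {
    df <- dplyr::mutate(streams[[nm]], dplyr::across(
      dplyr::where(function(x) inherits(x, "POSIXct")), fmt_iso
    ))
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, character(1))
  cfg <- cohort$config
  cfg$ema_windows <- lapply(cfg$ema_windows, as.numeric)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  jsonlite::write_json(
    lapply(unclass(cohort$truth), function(x)
      if (!is.null(names(x))) as.list(x) else x),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
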