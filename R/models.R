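#' Build the fixed-effect design for an iAUC association model
#'
#' Assembles the analysis formula and complete-case data for the
#' random-intercept models of postprandial glucose iAUC. In `basic` mode
#' the design holds one exposure (its within- and between-person parts)
#' plus the baseline covariates and meal-time category; in `full` mode
#' all exposures enter jointly (mutually adjusted). Person-mean centering
#' is applied automatically when the `_w`/`_b` columns are absent.
#'
#' @param events Meal-level analysis table: `participant_id`, `iauc_2h`,
#'   `time_category`, the exposures (see [ppgr_exposures]) and the
#'   baseline covariates (`age`, `sex`, `ethnicity`, `education`,
#'   `smoker`, `heavy_alcohol`, `bmi`, `preprandial_mean_2h`).
#' @param mode `"full"` (default) or `"basic"`.
#' @param exposure For `basic` mode, the single exposure name.
#' @param exposures Exposure set (default [ppgr_exposures] intersected
#'   with the data).
#' @param include_between Include the between-person exposure terms
#'   (default `TRUE`; the sensitivity analyses set this to `FALSE`).
#' @param drop_covariates Covariates to omit (e.g. the stratifying
#'   variable in stratified fits).
#' @return A list of class `ppgr_design`: `data` (complete cases),
#'   `formula`, `terms` (tibble mapping model terms to levels
#'   within/between/context), `n_dropped`.
#' @export
build_design <- function(events, mode = c("full", "basic"), exposure = NULL,
                         exposures = NULL, include_between = TRUE,
                         drop_covariates = character(0)) {
  mode <- match.arg(mode)
  events <- tibble::as_tibble(events)
  stopifnot_cols(events, c("participant_id", "iauc_2h", "time_category"),
                 "events")
  if (is.null(exposures)) exposures <- intersect(ppgr_exposures, names(events))
  if (mode == "basic") {
    if (is.null(exposure) || !exposure %in% exposures) {
      abort("basic mode needs a single canonical `exposure`")
    }
    exposures <- exposure
  }
  if (!all(paste0(exposures, "_w") %in% names(events))) {
    events <- person_center(events, exposures)
  }
  covars <- setdiff(intersect(ppgr_covariates, names(events)), drop_covariates)
  expo_terms <- c(
    paste0(exposures, "_w"),
    if (include_between) paste0(exposures, "_b")
  )
  rhs <- c(expo_terms, "time_category", covars)
  # categorical covariates with stated references
  events$time_category <- factor(events$time_category, levels = ppgr_time_levels)
  for (v in intersect(c("sex", "ethnicity", "education"), covars)) {
    lev <- switch(v,
      sex = c("female", "male"),
      ethnicity = c("Chinese", "Malay", "Indian"),
      education = c("secondary_or_below", "a_level", "university_or_above")
    )
    events[[v]] <- factor(as.character(events[[v]]), levels = lev)
  }
  need <- c("participant_id", "iauc_2h", rhs)
  cc <- stats::complete.cases(events[, need])
  n_dropped <- sum(!cc)
  data <- events[cc, , drop = FALSE]
  if (nrow(data) == 0) abort("zero usable rows after complete-case filtering")
  # unobserved factor levels in this subset would create all-zero dummy
  # columns; drop them (the stated reference order is kept)
  for (v in c("time_category", intersect(c("sex", "ethnicity", "education"),
                                         covars))) {
    data[[v]] <- droplevels(data[[v]])
  }
  # covariates that are constant in this subset (common in stratified fits)
  # carry no information; drop them rather than failing the rank check
  const_cov <- covars[vapply(covars, function(v)
    dplyr::n_distinct(data[[v]]) < 2, logical(1))]
  if (length(const_cov) > 0) {
    warn(sprintf("dropping constant covariate(s): %s",
                 paste(const_cov, collapse = ", ")))
    covars <- setdiff(covars, const_cov)
    rhs <- c(expo_terms, "time_category", covars)
  }
  f <- as.formula(paste("iauc_2h ~", paste(rhs, collapse = " + "),
                        "+ (1 | participant_id)"))
  X <- model.matrix(as.formula(paste("~", paste(rhs, collapse = " + "))), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  term_level <- function(tt) {
    dplyr::case_when(
      grepl("_w$", tt) ~ "within",
      grepl("_b$", tt) ~ "between",
      TRUE ~ "context"
    )
  }
  structure(list(
    data = data, formula = f,
    terms = tibble::tibble(term = rhs, level = term_level(rhs)),
    exposures = exposures, mode = mode, include_between = include_between,
    n_dropped = n_dropped
  ), class = "ppgr_design")
}

#' Fit the random-intercept association model
#'
#' Fits the linear mixed model of postprandial glucose iAUC on the
#' designed fixed effects with a person-specific random intercept, by
#' restricted maximum likelihood. Wald tests with Satterthwaite degrees
#' of freedom give the fixed-effect p-values.
#'
#' @param design A `ppgr_design` from [build_design()], or a meal-level
#'   events table (then `...` is passed on to [build_design()]).
#' @param ... Arguments forwarded to [build_design()] when `design` is a
#'   data frame.
#' @return An object of class `ppgr_fit` with elements `model` (the
#'   `lmerModLmerTest` fit), `design`, `coefficients` (tibble: `term`,
#'   `level`, `beta`, `se`, `df`, `p_value`), `converged`, `singular`,
#'   `note`.
#' @export
fit_iauc_model <- function(design, ...) {
  if (is.data.frame(design)) design <- build_design(design, ...)
  if (!inherits(design, "ppgr_design")) {
    abort("design must be a ppgr_design or a meal-level data frame")
  }
  note <- character(0)
  model <- withCallingHandlers(
    lmerTest::lmer(design$formula, data = design$data, REML = TRUE),
    message = function(m) {
      note <<- c(note, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      note <<- c(note, conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  sm <- suppressMessages(summary(model))$coefficients
  terms_tbl <- tibble::tibble(
    term = rownames(sm),
    beta = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    df = sm[, "df"],
    p_value = sm[, "Pr(>|t|)"]
  )
  base <- sub("_w$", "", sub("_b$", "", terms_tbl$term))
  terms_tbl$level <- dplyr::case_when(
    grepl("_w$", terms_tbl$term) & base %in% ppgr_exposures ~ "within",
    grepl("_b$", terms_tbl$term) & base %in% ppgr_exposures ~ "between",
    TRUE ~ "context"
  )
  vc <- lme4::VarCorr(model)
  structure(list(
    model = model, design = design,
    coefficients = terms_tbl[, c("term", "level", "beta", "se", "df", "p_value")],
    variance_components = c(between = as.numeric(vc$participant_id[1, 1]),
                            residual = attr(vc, "sc")^2),
    converged = length(model@optinfo$conv$lme4) == 0,
    singular = lme4::isSingular(model),
    note = paste(unique(trimws(note)), collapse = "; ")
  ), class = "ppgr_fit")
}

#' @export
print.ppgr_fit <- function(x, ...) {
  cat(sprintf(
    "<ppgr_fit> %s model: %d meals, %d participants, %d fixed effects\n",
    x$design$mode, nrow(x$design$data),
    dplyr::n_distinct(x$design$data$participant_id), nrow(x$coefficients)
  ))
  print(x$coefficients, n = 12)
  invisible(x)
}

#' Cluster-bootstrap confidence intervals
#'
#' Percentile 95% confidence intervals for the fixed effects, obtained by
#' resampling whole participants (clusters) with replacement and
#' refitting. Resampled copies of a participant are relabelled so they
#' enter the refit as distinct clusters. Replicates that fail to converge
#' are dropped and counted; the result is flagged when more than 10% of
#' replicates fail.
#'
#' @param fit A `ppgr_fit`.
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Integer seed (the resampling is fully reproducible).
#' @param level Confidence level (default 0.95).
#' @return The fit's coefficient tibble with `ci_low` and `ci_high`
#'   columns; attributes `B`, `seed`, `n_failed`, `flagged`.
#' @export
bootstrap_ci <- function(fit, B = 1000, seed = 1L, level = 0.95) {
  if (!inherits(fit, "ppgr_fit")) abort("fit must be a ppgr_fit")
  if (B < 200) abort("B must be >= 200")
  data <- fit$design$data
  ids <- unique(data$participant_id)
  rows_by_id <- split(seq_len(nrow(data)), data$participant_id)
  set.seed(as.integer(seed))
  fe_names <- names(lme4::fixef(fit$model))
  draws <- matrix(NA_real_, B, length(fe_names),
                  dimnames = list(NULL, fe_names))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(rows_by_id[as.character(take)], use.names = FALSE)
    d <- data[idx, , drop = FALSE]
    # relabel so each resampled copy is its own cluster
    d$participant_id <- rep(seq_along(take),
                            lengths(rows_by_id[as.character(take)]))
    est <- tryCatch(
      lme4::fixef(suppressMessages(suppressWarnings(
        lme4::lmer(fit$design$formula, data = d, REML = TRUE, control = ctrl)
      ))),
      error = function(e) NULL
    )
    # resamples can lose a rare factor level; the affected coefficient is
    # simply absent from that replicate (NA), the rest are kept
    if (!is.null(est)) draws[b, names(est)] <- est
  }
  n_failed <- sum(rowSums(!is.na(draws)) == 0)
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, na.rm = TRUE)
  out <- fit$coefficients
  m <- match(out$term, fe_names)
  out$ci_low <- qs[1, m]
  out$ci_high <- qs[2, m]
  attr(out, "B") <- B
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_failed") <- n_failed
  attr(out, "flagged") <- n_failed > 0.1 * B
  if (n_failed > 0.1 * B) {
    warn(sprintf("bootstrap flagged: %d of %d replicates failed to converge",
                 n_failed, B))
  }
  out
}

#' Exposure-by-modifier interaction tests
#'
#' Adds multiplicative interaction terms of a binary modifier (sex or
#' prediabetes status) with each within-person exposure to the full
#' mutually-adjusted model (between-person exposure terms are excluded,
#' as in the sensitivity analyses), and reports Wald p-values per
#' interaction. Flags: `significant` (p < 0.05), `marginal`
#' (0.05 <= p < 0.10), `ns`.
#'
#' @param events Meal-level analysis table (see [build_design()]); must
#'   contain the modifier column.
#' @param modifier `"sex"` or `"prediabetes"`.
#' @param exposures Exposure set (default canonical).
#' @return Tibble: `exposure`, `term`, `beta`, `se`, `p_value`, `flag`.
#' @export
interaction_test <- function(events, modifier = c("sex", "prediabetes"),
                             exposures = NULL) {
  modifier <- match.arg(modifier)
  stopifnot_cols(events, modifier, "events")
  mod_vals <- events[[modifier]]
  if (dplyr::n_distinct(mod_vals[!is.na(mod_vals)]) < 2) {
    abort(sprintf("modifier '%s' is constant in the data", modifier))
  }
  design <- build_design(events, mode = "full", exposures = exposures,
                         include_between = FALSE,
                         drop_covariates = modifier)
  d <- design$data
  d$.mod <- if (modifier == "sex") {
    as.numeric(factor(as.character(d$sex), levels = c("female", "male"))) - 1
  } else {
    as.numeric(as.logical(d$prediabetes))
  }
  expo_w <- paste0(design$exposures, "_w")
  rhs <- paste(c(all.vars(design$formula[[3]])[
    all.vars(design$formula[[3]]) != "participant_id"], ".mod",
    paste0(".mod:", expo_w)), collapse = " + ")
  f <- as.formula(paste("iauc_2h ~", rhs, "+ (1 | participant_id)"))
  model <- suppressMessages(suppressWarnings(
    lmerTest::lmer(f, data = d, REML = TRUE)
  ))
  sm <- suppressMessages(summary(model))$coefficients
  keep <- grepl("\\.mod", rownames(sm)) & grepl(":", rownames(sm))
  int_names <- rownames(sm)[keep]
  out <- tibble::tibble(
    exposure = sub("_w$", "", gsub("\\.mod|:", "", int_names)),
    term = paste0(modifier, ":", sub("_w$", "", gsub("\\.mod|:", "", int_names))),
    beta = sm[keep, "Estimate"],
    se = sm[keep, "Std. Error"],
    p_value = sm[keep, "Pr(>|t|)"],
    flag = dplyr::case_when(
      sm[keep, "Pr(>|t|)"] < 0.05 ~ "significant",
      sm[keep, "Pr(>|t|)"] < 0.10 ~ "marginal",
      TRUE ~ "ns"
    )
  )
  # the full coefficient table (main effects included) for callers that
  # need it without refitting
  attr(out, "model_coefficients") <- tibble::tibble(
    term = rownames(sm), beta = sm[, "Estimate"], se = sm[, "Std. Error"],
    p_value = sm[, "Pr(>|t|)"]
  )
  out
}

#' Stratified sensitivity analysis
#'
#' Refits the full mutually-adjusted model separately within strata of
#' sex or prediabetes status. The stratifying variable is removed from
#' the covariates and the between-person exposure terms are excluded (as
#' in the interaction models) to limit the loss of power in the smaller
#' subgroups.
#'
#' @param events Meal-level analysis table including the stratifier.
#' @param strata_var `"sex"` or `"prediabetes"`.
#' @param exposures Exposure set (default canonical).
#' @return Tibble of per-stratum coefficient estimates with a `stratum`
#'   column (`male`/`female` or `prediabetes`/`no_prediabetes`); strata
#'   with fewer than 2 participants are skipped with a warning.
#' @export
stratified_fit <- function(events, strata_var = c("sex", "prediabetes"),
                           exposures = NULL) {
  strata_var <- match.arg(strata_var)
  stopifnot_cols(events, strata_var, "events")
  vals <- events[[strata_var]]
  strata <- if (strata_var == "sex") {
    list(male = vals == "male", female = vals == "female")
  } else {
    list(prediabetes = as.logical(vals), no_prediabetes = !as.logical(vals))
  }
  purrr::map_dfr(names(strata), function(s) {
    sub <- events[which(strata[[s]]), , drop = FALSE]
    if (dplyr::n_distinct(sub$participant_id) < 2) {
      warn(sprintf("stratum '%s' has < 2 participants; skipped", s))
      return(tibble::tibble())
    }
    fit <- fit_iauc_model(sub, mode = "full", exposures = exposures,
                          include_between = FALSE,
                          drop_covariates = strata_var)
    dplyr::mutate(fit$coefficients, stratum = s, .before = 1)
  })
}
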