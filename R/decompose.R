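#' Person-mean centering of longitudinal exposures
#'
#' Splits each repeated meal-level exposure into a between-person
#' component (the person mean, constant within participant, optionally
#' grand-mean centered) and a within-person component (the occasion value
#' minus the person mean). By construction `within + person mean`
#' reconstructs the original value and the within components sum to zero
#' within each participant.
#'
#' @param data Meal-level data frame containing `participant_id` and the
#'   exposure columns.
#' @param exposures Character vector of exposure column names (default:
#'   the canonical exposures present in `data`). Binary flags are coerced
#'   to 0/1.
#' @param grand_center Subtract the grand mean from the between component
#'   (default `TRUE`; makes the model intercept interpretable, slopes are
#'   unaffected).
#' @param suffix Two suffixes for the within and between columns.
#' @return `data` with a `<name>_w` and `<name>_b` column per exposure.
#'   Participants with all-missing values for an exposure get `NA` in both
#'   components; occasion-level missing values get `NA` within and the
#'   person mean over non-missing occasions between.
#' @export
person_center <- function(data, exposures = NULL, grand_center = TRUE,
                          suffix = c("_w", "_b")) {
  stopifnot_cols(data, "participant_id", "data")
  if (is.null(exposures)) exposures <- intersect(ppgr_exposures, names(data))
  stopifnot_cols(data, exposures, "data")
  data <- tibble::as_tibble(data)
  out <- data |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(exposures),
      list(
        w = function(x) {
          x <- as.numeric(x)
          x - mean(x, na.rm = TRUE)
        },
        b = function(x) {
          x <- as.numeric(x)
          m <- mean(x, na.rm = TRUE)
          rep(if (is.nan(m)) NA_real_ else m, length(x))
        }
      ),
      .names = "{.col}__tmp_{.fn}"
    )) |>
    dplyr::ungroup()
  for (e in exposures) {
    w <- out[[paste0(e, "__tmp_w")]]
    b <- out[[paste0(e, "__tmp_b")]]
    w[is.nan(w)] <- NA_real_
    if (grand_center) b <- b - mean(b, na.rm = TRUE)
    out[[paste0(e, suffix[1])]] <- w
    out[[paste0(e, suffix[2])]] <- b
    out[[paste0(e, "__tmp_w")]] <- NULL
    out[[paste0(e, "__tmp_b")]] <- NULL
  }
  out
}

#' Intraclass correlation of a continuous repeated measure
#'
#' Fits an intercept-only linear mixed model with a person random
#' intercept and reports the share of total variance between persons,
#' `icc = s2_between / (s2_between + s2_within)`. The within-person share
#' is `1 - icc`.
#'
#' @param data Data frame with `participant_id` and the measure column.
#' @param measure Name of the measure column (string).
#' @return One-row tibble: `measure`, `scale`, `icc`, `between_var`,
#'   `within_var`, `n_participants`, `n_obs`, `note` (convergence
#'   diagnostics, empty when clean).
#' @export
icc_continuous <- function(data, measure) {
  stopifnot_cols(data, c("participant_id", measure), "data")
  d <- tibble::tibble(
    y = as.numeric(data[[measure]]),
    id = factor(data$participant_id)
  )
  d <- d[!is.na(d$y), , drop = FALSE]
  if (dplyr::n_distinct(d$id) < 2) abort("need >= 2 participants for an ICC")
  note <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(y ~ 1 + (1 | id), data = d,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    message = function(m) {
      note <<- c(note, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      note <<- c(note, conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  vc <- lme4::VarCorr(fit)
  s2_b <- as.numeric(vc$id[1, 1])
  s2_w <- attr(vc, "sc")^2
  if (lme4::isSingular(fit)) note <- c(note, "singular fit")
  tibble::tibble(
    measure = measure, scale = "continuous",
    icc = s2_b / (s2_b + s2_w), between_var = s2_b, within_var = s2_w,
    n_participants = dplyr::n_distinct(d$id), n_obs = nrow(d),
    note = paste(unique(trimws(note)), collapse = "; ")
  )
}

#' Latent-scale intraclass correlation of a binary repeated measure
#'
#' Fits an intercept-only logistic mixed model with a person random
#' intercept; on the latent (liability) scale the residual variance is
#' `pi^2/3`, so `icc = s2_between / (s2_between + pi^2/3)`.
#'
#' @inheritParams icc_continuous
#' @return One-row tibble with the same columns as [icc_continuous()],
#'   `scale = "binary_latent"`.
#' @export
icc_binary <- function(data, measure) {
  stopifnot_cols(data, c("participant_id", measure), "data")
  d <- tibble::tibble(
    y = as.numeric(data[[measure]]),
    id = factor(data$participant_id)
  )
  d <- d[!is.na(d$y), , drop = FALSE]
  if (!all(d$y %in% c(0, 1))) abort(sprintf("'%s' is not binary 0/1", measure))
  if (length(unique(d$y)) < 2) {
    abort(sprintf("'%s' has a single outcome level; latent ICC is undefined", measure))
  }
  note <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(y ~ 1 + (1 | id), data = d, family = stats::binomial(),
                nAGQ = 1L),
    message = function(m) {
      note <<- c(note, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      note <<- c(note, conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  s2_b <- as.numeric(lme4::VarCorr(fit)$id[1, 1])
  s2_w <- pi^2 / 3
  if (lme4::isSingular(fit)) note <- c(note, "singular fit")
  tibble::tibble(
    measure = measure, scale = "binary_latent",
    icc = s2_b / (s2_b + s2_w), between_var = s2_b, within_var = s2_w,
    n_participants = dplyr::n_distinct(d$id), n_obs = nrow(d),
    note = paste(unique(trimws(note)), collapse = "; ")
  )
}

#' Variance decomposition of the longitudinal measures
#'
#' Computes the ICC (between-person variance share) and its complement
#' (within-person share) for each longitudinal measure, using the linear
#' mixed model for continuous measures and the logistic mixed model for
#' binary flags.
#'
#' @param data Meal-level data frame with `participant_id` and the
#'   measure columns.
#' @param measures Character vector of measure names (default: the
#'   canonical exposures present plus `iauc_2h` if present).
#' @return Tibble with one row per measure: the [icc_continuous()] /
#'   [icc_binary()] columns plus `within_share = 1 - icc` and
#'   `between_share = icc`.
#' @export
variance_decomposition <- function(data, measures = NULL) {
  if (is.null(measures)) {
    measures <- intersect(c(ppgr_exposures, "iauc_2h"), names(data))
  }
  out <- purrr::map_dfr(measures, function(m) {
    x <- data[[m]][!is.na(data[[m]])]
    binary <- all(as.numeric(x) %in% c(0, 1))
    if (binary) icc_binary(data, m) else icc_continuous(data, m)
  })
  dplyr::mutate(out, between_share = .data$icc, within_share = 1 - .data$icc)
}
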