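#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the coefficients of a fitted iAUC model
#'
#' @param x A `ppgr_fit`.
#' @param conf_int A bootstrap CI table from [bootstrap_ci()] to merge in,
#'   or `NULL`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `level`
#'   (within/between/context), `estimate`, `std.error`, `df`, `p.value`
#'   and, when available, `conf.low`/`conf.high`.
#' @method tidy ppgr_fit
#' @export
tidy.ppgr_fit <- function(x, conf_int = NULL, ...) {
  out <- x$coefficients |>
    dplyr::rename(estimate = "beta", std.error = "se", p.value = "p_value")
  if (!is.null(conf_int)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(conf_int, "term", conf.low = "ci_low", conf.high = "ci_high"),
      by = "term"
    )
  }
  out
}

#' One-row model summary of a fitted iAUC model
#'
#' @param x A `ppgr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: numbers of meals and participants, variance
#'   components and the derived ICC of the outcome residual structure,
#'   REML criterion, convergence and singularity flags.
#' @method glance ppgr_fit
#' @export
glance.ppgr_fit <- function(x, ...) {
  vc <- x$variance_components
  tibble::tibble(
    n_meals = nrow(x$design$data),
    n_participants = dplyr::n_distinct(x$design$data$participant_id),
    n_fixed_effects = nrow(x$coefficients),
    var_between = vc[["between"]],
    var_residual = vc[["residual"]],
    icc = vc[["between"]] / (vc[["between"]] + vc[["residual"]]),
    REML_criterion = as.numeric(stats::deviance(x$model, REML = TRUE)),
    converged = x$converged,
    singular = x$singular
  )
}
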