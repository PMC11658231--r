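#' Stacked within/between variance-share chart
#'
#' Displays, for each longitudinal measure, the share of total variance
#' attributable to within-person fluctuation versus stable between-person
#' differences (the ICC).
#'
#' @param vd Output of [variance_decomposition()].
#' @return A ggplot object.
#' @export
plot_variance_decomposition <- function(vd) {
  stopifnot_cols(vd, c("measure", "within_share", "between_share"), "vd")
  long <- vd |>
    dplyr::mutate(measure = stats::reorder(.data$measure, .data$within_share)) |>
    tidyr::pivot_longer(c("within_share", "between_share"),
                        names_to = "component", values_to = "share") |>
    dplyr::mutate(component = factor(
      sub("_share", "-person", .data$component),
      levels = c("between-person", "within-person")
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$share, y = .data$measure, fill = .data$component
  )) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%"),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "share of total variance", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of exposure associations
#'
#' Point estimates (and bootstrap CIs when supplied) of the within- and
#' between-person exposure effects on the 2-h postprandial iAUC.
#'
#' @param object A `ppgr_fit`.
#' @param conf_int Optional [bootstrap_ci()] table.
#' @param level Which coefficient levels to show (default within and
#'   between).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppgr_fit
#' @export
autoplot.ppgr_fit <- function(object, conf_int = NULL,
                              level = c("within", "between"), ...) {
  td <- tidy(object, conf_int = conf_int) |>
    dplyr::filter(.data$level %in% .env$level) |>
    dplyr::mutate(term = stats::reorder(.data$term, .data$estimate))
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term,
                                        colour = .data$level)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point()
  if (all(c("conf.low", "conf.high") %in% names(td))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.25
    )
  }
  p +
    ggplot2::labs(x = "effect on 2-h iAUC (mmol/l*min)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of stratified estimates
#'
#' @param strat Output of [stratified_fit()].
#' @param level Coefficient level to display (default `"within"`).
#' @return A ggplot object.
#' @export
plot_stratified <- function(strat, level = "within") {
  stopifnot_cols(strat, c("stratum", "term", "beta"), "strat")
  d <- dplyr::filter(strat, .data$level %in% .env$level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$term,
                                  colour = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "effect on 2-h iAUC (mmol/l*min)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
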