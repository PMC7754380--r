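#' Interval plot of an NMA fit
#'
#' Posterior means and 95% credible intervals of the basic parameters (and
#' `tau2`, shown with its posterior median).
#'
#' @param object An `nma_fit`.
#' @param parameters Passed to [tidy.nma_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nma_fit
#' @export
autoplot.nma_fit <- function(object, parameters = "basic", ...) {
  td <- tidy(object, parameters = parameters)
  td$point <- ifelse(td$term == "tau2", td$median, td$estimate)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$point, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior estimate (95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Rankogram
#'
#' Per-intervention distribution of posterior rank probabilities.
#'
#' @param object An `nma_ranks` from [rank_probabilities()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nma_ranks
#' @export
autoplot.nma_ranks <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rank, y = .data$probability,
                               colour = .data$intervention,
                               group = .data$intervention)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$rank)) +
    ggplot2::labs(x = "rank", y = "probability") +
    ggplot2::theme_minimal()
}

#' Interval plot across models
#'
#' Renders an [interval_table()] (one row per estimand and model) as a
#' faceted interval plot, the layout used to compare missingness models and
#' log-IMOR prior structures.
#'
#' @param tbl Output of [interval_table()].
#' @return A ggplot.
#' @export
plot_intervals <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$point, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~estimand, scales = "free_x") +
    ggplot2::labs(x = "posterior estimate (95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}
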