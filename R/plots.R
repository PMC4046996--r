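# ggplot2 views of the analysis objects.

#' Cost-effectiveness plane of a PSA
#'
#' One point per (draw, strategy); crosses mark per-strategy means.
#'
#' @param object a `psa_result`.
#' @param alpha point transparency.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.psa_result <- function(object, alpha = 0.2, ...) {
  means <- mean_outcomes(object)
  ggplot2::ggplot(object$outcomes,
                  ggplot2::aes(x = .data$qalys, y = .data$cost_total,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::geom_point(data = means, shape = 4, size = 3,
                        stroke = 1.5, colour = "black") +
    ggplot2::labs(x = "Discounted QALYs per household",
                  y = "Discounted cost per household (GBP)",
                  colour = "Strategy",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Frontier plot
#'
#' Expected cost against expected QALYs per strategy, with the
#' cost-effectiveness frontier drawn through the non-dominated strategies.
#'
#' @param object a `cea_frontier`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cea_frontier <- function(object, ...) {
  tab <- tidy(object)
  fr <- tab[tab$status == "frontier", ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$qalys, y = .data$cost)) +
    ggplot2::geom_line(data = fr, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Expected QALYs", y = "Expected cost (GBP)",
                  colour = NULL, title = "Cost-effectiveness frontier") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param object a `cea_ceac`.
#' @param ... unused.
#' @return A ggplot: probability of being cost-effective against the
#'   willingness-to-pay threshold, one curve per strategy.
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$threshold, y = .data$probability,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability cost-effective", colour = "Strategy",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' EVPI against the willingness-to-pay threshold
#'
#' @param object a `cea_evpi` (e.g. from [evpi_curve()]).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cea_evpi <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$threshold, y = .data$evpi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Per-decision EVPI (GBP)",
                  title = "Expected value of perfect information") +
    ggplot2::theme_minimal()
}
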