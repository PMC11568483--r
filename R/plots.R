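# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_hline geom_tile
#'   geom_line geom_point facet_wrap labs scale_fill_gradient theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Boxplots of estimator bias per condition
#'
#' @param object A `sirel_results` tibble from [run_study()].
#' @param ... Unused.
#' @return A ggplot: bias by method, one facet per condition, with a zero
#'   reference line.
#' @method autoplot sirel_results
#' @export
autoplot.sirel_results <- function(object, ...) {
  ok <- dplyr::filter(object, .data$status == "ok")
  ggplot(ok, aes(x = .data$method, y = .data$bias)) +
    geom_boxplot(outlier.size = 0.5) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    facet_wrap(~condition) +
    labs(x = NULL, y = "bias (estimate - true reliability)") +
    theme_minimal()
}

#' Heatmap of an ordered joint cumulative probability matrix
#'
#' @param object A `sirel_joint_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map; unobservable cells are blank.
#' @method autoplot sirel_joint_matrix
#' @export
autoplot.sirel_joint_matrix <- function(object, ...) {
  d <- tidy(object)
  d$row_lab <- sprintf("%s>=%d", d$row_item, d$row_level)
  d$col_lab <- sprintf("%s>=%d", d$col_item, d$col_level)
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile(colour = "grey80") +
    scale_fill_gradient(low = "white", high = "steelblue", na.value = "grey95") +
    labs(x = "column (ascending marginal)", y = "row (ascending marginal)",
         fill = "joint cum. prob.") +
    theme_minimal()
}

#' Log-likelihood trace of a latent class fit
#'
#' @param object A `sirel_lcm` fit.
#' @param ... Unused.
#' @return A ggplot of the EM log-likelihood path of the best start.
#' @method autoplot sirel_lcm
#' @export
autoplot.sirel_lcm <- function(object, ...) {
  d <- tibble::tibble(iteration = seq_along(object$trace), loglik = object$trace)
  ggplot(d, aes(x = .data$iteration, y = .data$loglik)) +
    geom_line() + geom_point(size = 0.8) +
    labs(y = "log-likelihood") +
    theme_minimal()
}

#' Median bias per condition and method
#'
#' @param object A `sirel_summary` tibble from [summarize_condition()].
#' @param ... Unused.
#' @return A ggplot of median bias by condition, coloured by method.
#' @method autoplot sirel_summary
#' @export
autoplot.sirel_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$condition, y = .data$median_bias,
                     colour = .data$method)) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_point() + geom_line() +
    labs(x = "condition", y = "median bias", colour = "method") +
    theme_minimal()
}
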