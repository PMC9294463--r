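#' Observed-versus-calculated plot for a fitted model
#'
#' @param object an `mlr_model`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mlr_model
#' @export
autoplot.mlr_model <- function(object, ...) {
  d <- tibble::tibble(id = object$ids, observed = object$y,
                      calculated = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$calculated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("observed %s", object$response),
      y = sprintf("calculated %s", object$response),
      title = sprintf("OLS fit, n = %d, p = %d", object$n, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Williams plot of the applicability domain
#'
#' Leverage against standardized residual, with the warning leverage
#' \eqn{h^* = 3p'/n} and the residual thresholds drawn in; flagged
#' compounds are labelled.
#'
#' @param object an `ad_report` from [williams_domain()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ad_report
#' @export
autoplot.ad_report <- function(object, ...) {
  h_star <- attr(object, "h_star")
  thr <- attr(object, "res_threshold")
  d <- tibble::as_tibble(object)
  flagged <- dplyr::filter(d, .data$outlier | .data$high_leverage)
  ggplot2::ggplot(d, ggplot2::aes(.data$leverage, .data$std_residual)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = h_star, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier |
                                       .data$high_leverage),
                        show.legend = FALSE) +
    ggplot2::geom_text(data = flagged,
                       ggplot2::aes(label = .data$id),
                       nudge_y = 0.15, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "leverage h", y = "standardized residual",
                  title = sprintf("Williams plot (h* = %.3f)", h_star)) +
    ggplot2::theme_minimal()
}

#' Null-distribution plot for a Y-scrambling run
#'
#' @param object a `y_scramble` result.
#' @param ... unused.
#' @return A ggplot showing the scrambled R-squared distribution and its
#'   mean.
#' @method autoplot y_scramble
#' @export
autoplot.y_scramble <- function(object, ...) {
  d <- tibble::tibble(r2 = object$r2)
  ggplot2::ggplot(d, ggplot2::aes(.data$r2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$r2_mean, colour = "red") +
    ggplot2::labs(
      x = expression(R^2 ~ "of scrambled refits"),
      y = "count",
      title = sprintf("Y-scrambling: %d permutations, mean R2 = %.3f",
                      object$n_perm, object$r2_mean)
    ) +
    ggplot2::theme_minimal()
}
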