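#' QQ plot of p-values
#'
#' @param p_vector Numeric p-values (or a [scan_genes()] result, whose
#'   `p_value` column is used).
#' @param cap Upper cap on the `-log10(p)` axis (see [qq_data()]).
#' @return A ggplot: observed vs expected `-log10(p)` with the identity
#'   line in red.
#' @export
plot_qq <- function(p_vector, cap = 320) {
  if (is.data.frame(p_vector) && "p_value" %in% names(p_vector)) {
    p_vector <- p_vector$p_value
  }
  qq <- qq_data(p_vector)
  qq$observed <- pmin(qq$observed, cap)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_qq
#' @param object A `scan_result` from [scan_genes()].
#' @param ... Unused.
#' @export
autoplot.scan_result <- function(object, ...) {
  plot_qq(object$p_value) +
    ggplot2::ggtitle(unique(object$method))
}

#' Type I error profile across methods
#'
#' Empirical rejection rates with 2 Monte-Carlo-SE error bars against the
#' nominal level (dashed), one panel per significance level.
#'
#' @param object A `type1_result` from [run_type1_experiment()].
#' @param ... Unused.
#' @export
autoplot.type1_result <- function(object, ...) {
  d <- dplyr::mutate(object,
    test = ifelse(is.na(.data$m), .data$method,
      paste0(.data$method, " (m=", .data$m, ")")
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$rate - 2 * .data$mc_se, 0),
        ymax = .data$rate + 2 * .data$mc_se
      ),
      width = 0.3
    ) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~alpha, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "empirical type I error") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Power curves over the grade-effect grid
#'
#' @param object A `power_result` from [run_power_experiment()].
#' @param ... Unused.
#' @export
autoplot.power_result <- function(object, ...) {
  d <- dplyr::mutate(object,
    test = ifelse(is.na(.data$m), .data$method,
      paste0(.data$method, " (m=", .data$m, ")")
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$beta1, y = .data$rate,
    colour = .data$test
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(beta[1] ~ "(grade log fold change)"),
      y = "power", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
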