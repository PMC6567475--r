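#' @export
autoplot.rg_degree_distribution <- function(object, ...) {
  d <- filter(as_tibble(object), .data$degree >= 1L, .data$probability > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(k)",
                  title = sprintf("%s-degree distribution",
                                  object$kind[1])) +
    ggplot2::theme_minimal()
}

#' Log-log degree distribution plot with the fitted power law
#'
#' @param g A [reaction_graph()].
#' @param kind Degree kind, see [degree_distribution()].
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(g, kind = "total") {
  dist <- degree_distribution(g, kind)
  p <- autoplot(dist)
  fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, linewidth = 0.4) +
      ggplot2::labs(subtitle = sprintf("log-log LS slope gamma = %.2f",
                                       fit$gamma))
  }
  p
}

#' @export
autoplot.rg_binned_essentiality <- function(object, ...) {
  d <- as_tibble(object) %>%
    tidyr::pivot_longer(c("n_essential", "n_total"), names_to = "what",
                        values_to = "count") %>%
    mutate(what = ifelse(.data$what == "n_essential", "essential", "total"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$bin), y = .data$count,
                                  fill = .data$what)) +
    ggplot2::geom_col(position = "identity", alpha = 0.7) +
    ggplot2::scale_fill_manual(values = c(essential = "black",
                                          total = "grey70")) +
    ggplot2::labs(x = "metric bin", y = "reactions", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rg_cascade_essentiality <- function(object, ...) {
  d <- filter(as_tibble(object), .data$n_leading > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin,
                                  y = .data$percent_essential)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "cascade number", y = "% essential leading reactions",
                  subtitle = sprintf("Pearson r = %.2f",
                                     attr(object, "pearson_r"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rg_null_summary <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null_modularity)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_modularity,
                        color = "red") +
    ggplot2::labs(x = "null modularity Q",
                  subtitle = sprintf("observed Q = %.3f, p = %.3g",
                                     object$observed_modularity,
                                     object$empirical_p)) +
    ggplot2::theme_minimal()
}
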