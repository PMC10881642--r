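#' Heatmap of a connectivity or delta matrix
#'
#' @param x A `connectivity_matrix` or `delta_connectivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(x, ...) {
  if (inherits(x, "connectivity_matrix")) {
    df <- tidy(x)
    df$value <- df$z
    lab <- "Fisher z"
    ttl <- paste("Metabolic connectivity:", paste(x$group, collapse = "+"))
  } else {
    df <- tidy(x)
    df$value <- df$dz
    lab <- expression(Delta * "z")
    ttl <- paste("Connectivity change:", x$contrast[1], "vs", x$contrast[2])
  }
  df2 <- df
  names(df2)[1:2] <- c("region_j", "region_i")
  df <- dplyr::bind_rows(df, df2)
  df$region_i <- factor(df$region_i, levels = x$regions)
  df$region_j <- factor(df$region_j, levels = x$regions)
  ggplot2::ggplot(df, ggplot2::aes(.data$region_j, .data$region_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "purple4", name = lab) +
    ggplot2::labs(title = ttl, x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' @export
autoplot.connectivity_matrix <- function(object, ...) plot_connectivity(object, ...)

#' @export
autoplot.delta_connectivity <- function(object, ...) plot_connectivity(object, ...)

#' ROC curve plot
#'
#' @param x A `dlb_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_roc <- function(x, ...) {
  ggplot2::ggplot(x$curve, ggplot2::aes(1 - .data$specificity,
                                        .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", x$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dlb_roc <- function(object, ...) plot_roc(object, ...)

#' Expression-score distribution by group
#'
#' @param x A `dlb_expression` (optionally combined with the training
#'   scores first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_expression <- function(x, ...) {
  df <- if (inherits(x, "dlb_expression")) x$scores else x
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$z_score)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = NULL, y = "pattern expression (z vs HC)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dlb_expression <- function(object, ...) plot_expression(object, ...)

#' Effect-size similarity scatter plot
#'
#' Plots one 77-region Cohen's d profile against another with the OLS fit.
#'
#' @param d_a,d_b Effect-size vectors.
#' @param labels Axis labels.
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(d_a, d_b,
                              labels = c("Cohen's d (DaT+ vs HC)",
                                         "Cohen's d (DaT- vs HC)")) {
  df <- tibble::tibble(a = d_a, b = d_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = labels[1], y = labels[2]) +
    ggplot2::theme_minimal()
}
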