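# ggplot2 helpers for the main result types.

#' Volcano plot of a moderated contrast
#'
#' @param contrast An `ev_contrast` tibble.
#' @param alpha FDR threshold used for coloring (defaults to the contrast's
#'   own threshold).
#' @return A ggplot object.
#' @export
plot_volcano <- function(contrast, alpha = attr(contrast, "alpha") %||% 0.05) {
  g <- attr(contrast, "groups")
  df <- tidy(contrast) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$q_value < alpha & .data$log2fc > 0 ~ paste("up in", g[["a"]]),
      .data$q_value < alpha & .data$log2fc < 0 ~ paste("up in", g[["b"]]),
      TRUE ~ "not significant"))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c("grey60", "#1b7837", "#d73027") |>
                                   setNames(c("not significant",
                                              paste("up in", g[["b"]]),
                                              paste("up in", g[["a"]])))) +
    ggplot2::labs(x = sprintf("log2 fold change (%s - %s)", g[["a"]], g[["b"]]),
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked %Np category contributions per sample
#'
#' @param summary A `category_summary` tibble.
#' @return A ggplot object.
#' @export
plot_category_np <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$sample, .data$pct_np,
                                        fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "% of precursors (Np)", fill = "MISEV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Kaplan-Meier step curves for a quantile split
#'
#' @param object A `km_split` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_split <- function(object, ...) {
  anchors <- object$curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(anchors,
                         object$curves[c("group", "time", "survival")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(low = "#2166ac", high = "#b2182b")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Relapse-free survival",
                  colour = object$protein,
                  subtitle = sprintf("q = %.2f split; log-rank p = %.3g",
                                     object$q, object$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Particle-size histogram with its Gaussian fit
#'
#' @param object A `size_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.size_fit <- function(object, ...) {
  grid <- tibble::tibble(mid = seq(object$window[1], object$window[2],
                                   length.out = 400))
  grid$fit <- object$amplitude *
    exp(-(grid$mid - object$mean_nm)^2 / (2 * object$sd_nm^2))
  ggplot2::ggplot(object$histogram, ggplot2::aes(.data$mid,
                                                 .data$frequency)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "#b2182b") +
    ggplot2::labs(x = "Size (nm)", y = "Relative frequency",
                  subtitle = sprintf("Gaussian fit: mean %.1f nm, SD %.1f nm",
                                     object$mean_nm, object$sd_nm)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
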