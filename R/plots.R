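# Presentation helpers: comodulogram heat maps and polar phase plots.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Comodulogram heat map
#'
#' One tile per grid cell, coloured by `m_norm`. For a cohort grid table
#' the cells are first averaged within each group and the panels are
#' facetted by group and region.
#'
#' @param object a `pac_grid` or `pac_grids` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pac_grid <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$group, .data$region, .data$phase_lo, .data$amp_lo) |>
    dplyr::summarise(m_norm = mean(.data$m_norm), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$phase_lo + 0.5, y = .data$amp_lo + 0.5, fill = .data$m_norm
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$region), cols = ggplot2::vars(.data$group)
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "phase frequency (Hz)", y = "amplitude frequency (Hz)",
      fill = expression(M[norm])
    ) +
    ggplot2::theme_minimal()
}

#' T-map of a cluster permutation test, with significant cells marked
#'
#' @param object a `pac_cluster_test`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pac_cluster_test <- function(object, ...) {
  tm <- object$tmap
  sig <- significant_cells(object)
  p <- ggplot2::ggplot(tm, ggplot2::aes(
    x = .data$phase_lo + 0.5, y = .data$amp_lo + 0.5, fill = .data$t
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(
      title = sprintf("%s: %s vs %s", object$region,
                      object$groups["a"], object$groups["b"]),
      x = "phase frequency (Hz)", y = "amplitude frequency (Hz)", fill = "t"
    ) +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_tile(
      data = sig,
      ggplot2::aes(x = .data$phase_lo + 0.5, y = .data$amp_lo + 0.5),
      fill = NA, colour = "black", linewidth = 0.7, inherit.aes = FALSE
    )
  }
  p
}

#' Polar plot of per-subject phase angles
#'
#' Points on the unit circle at each subject's mean phase angle, with a
#' radial segment at each group's circular mean.
#'
#' @param summary a `pac_phase_summary` from [phase_angle_contrast()], or a
#'   tibble with `group` and `angle_deg` columns.
#' @param group_labels optional length-2 labels when `summary` is a
#'   `pac_phase_summary`.
#' @return a ggplot object.
#' @export
plot_phase_polar <- function(summary, group_labels = c("A", "B")) {
  if (inherits(summary, "pac_phase_summary")) {
    df <- tibble::tibble(
      group = rep(group_labels, c(length(summary$angles_a), length(summary$angles_b))),
      angle_deg = c(summary$angles_a, summary$angles_b)
    )
    means <- tibble::tibble(
      group = group_labels,
      angle_deg = c(summary$circ_mean_a, summary$circ_mean_b)
    )
  } else {
    stopifnot(is.data.frame(summary),
              all(c("group", "angle_deg") %in% names(summary)))
    df <- summary
    means <- df |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(angle_deg = circular_mean_deg(.data$angle_deg),
                       .groups = "drop")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(y = 1), alpha = 0.7) +
    ggplot2::geom_segment(
      data = means,
      ggplot2::aes(x = .data$angle_deg, xend = .data$angle_deg, y = 0, yend = 1),
      linetype = "dashed", linewidth = 0.8
    ) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270)) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05), breaks = NULL) +
    ggplot2::labs(x = NULL, y = NULL, colour = "group") +
    ggplot2::theme_minimal()
}
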