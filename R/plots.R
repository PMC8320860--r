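# ggplot2 displays for tracks, angle tables and comparisons.

#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_point geom_boxplot
#'   geom_hline geom_jitter labs scale_y_reverse theme_minimal coord_fixed
NULL

#' @export
ggplot2::autoplot

#' Plot tracks in image coordinates
#'
#' Draws each track as a path; points that are inside a clump are
#' highlighted. The y axis is reversed so the plot matches the image row
#' orientation.
#'
#' @param tracks Tracks tibble.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks) {
  ggplot(tracks, aes(x, y, group = track_label, colour = factor(track_label))) +
    geom_path(linewidth = 0.4) +
    geom_point(
      data = filter(tracks, clump_code != 0), size = 0.8, shape = 4
    ) +
    scale_y_reverse() +
    coord_fixed() +
    labs(colour = "track", x = "x (px)", y = "y (px)") +
    theme_minimal()
}

#' Boxplots of contact vs. control direction changes
#'
#' @param object An angle table from [measure_angles()] or a
#'   `contact_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_comparison <- function(object, ...) {
  long <- tibble(
    kind = rep(c("contact", "control"),
      c(length(object$group_contact), length(object$group_control))
    ),
    theta_deg = c(object$group_contact, object$group_control)
  )
  plot_angle_groups(long)
}

#' @rdname autoplot.contact_comparison
#' @param angles Angle table with `kind` and `theta_deg` columns.
#' @export
plot_angle_groups <- function(angles) {
  ggplot(
    filter(angles, !is.na(theta_deg)),
    aes(kind, theta_deg, colour = kind)
  ) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    labs(
      x = NULL, y = expression(theta[x] ~ "(degrees)"),
      colour = NULL
    ) +
    theme_minimal()
}
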