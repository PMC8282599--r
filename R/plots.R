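# ggplot2 views of the main result objects.

#' Plot a thickness map
#'
#' Raster view of the ray-traced thickness over the scan aperture, with the
#' central measurement zone outlined.
#'
#' @param object a `thickness_map`.
#' @param zone_diameter diameter (um) of the zone circle to draw.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.thickness_map <- function(object, zone_diameter = 2000, ...) {
  df <- tibble::tibble(
    x = rep(object$x, times = length(object$y)),
    y = rep(object$y, each = length(object$x)),
    thickness = as.vector(object$thickness),
    valid = as.vector(object$mask))
  df <- df[df$valid, ]
  th <- seq(0, 2 * pi, length.out = 181)
  circ <- tibble::tibble(x = zone_diameter / 2 * cos(th),
                         y = zone_diameter / 2 * sin(th))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$thickness)) +
    ggplot2::geom_raster() +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "thickness (um)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = paste0("Ray-traced thickness: ", object$layer))
}

#' Plot a cutpoint sweep as a forest-style panel
#'
#' Hazard ratios (log scale) with Wald 95% intervals per En/DMT cutpoint.
#'
#' @param object a `sweep_table`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sweep_table <- function(object, ...) {
  df <- object[object$status == "ok", ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cutpoint_um), y = .data$hazard.ratio)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "En/DMT cutpoint (um)", y = "hazard ratio (95% CI)",
                  title = "Rejection risk after En/DMT threshold crossing")
}

#' Spaghetti plot of longitudinal En/DMT (or CCT) trajectories
#'
#' One line per graft against follow-up month, coloured by outcome group;
#' rejected grafts show pre-rejection measurements only.
#'
#' @param cohort a `cohort_table`.
#' @param measure `"endmt"` or `"cct"`.
#' @param cutpoint optional horizontal reference threshold (um).
#' @return A ggplot.
#' @export
plot_cohort <- function(cohort, measure = c("endmt", "cct"), cutpoint = 19) {
  measure <- match.arg(measure)
  col <- paste0(measure, "_um")
  df <- tibble::as_tibble(cohort)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$visit_month, y = .data[[col]],
                                        group = .data$patient_id,
                                        colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "postoperative month",
                  y = paste0(toupper(measure), " (um)"), colour = NULL)
  if (!is.null(cutpoint) && measure == "endmt")
    p <- p + ggplot2::geom_hline(yintercept = cutpoint, linetype = 2)
  p
}
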