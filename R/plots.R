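#' Plot a spectrum
#'
#' @param object A `voxdose_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voxdose_spectrum
#' @export
autoplot.voxdose_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$energy_kev, .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Energy (keV)", y = "Relative fluence per keV") +
    ggplot2::theme_minimal()
}

#' Plot cohort comparison results
#'
#' Mean +/- SD percentage difference per organ, faceted by comparison.
#'
#' @param object A `voxdose_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voxdose_comparison
#' @export
autoplot.voxdose_comparison <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(.data$organ, .data$mean_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_pct - .data$sd_pct,
      ymax = .data$mean_pct + .data$sd_pct)) +
    ggplot2::facet_wrap(~comparison, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Organ dose difference (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an axial slice of a dose grid
#'
#' @param dose A `voxdose_dose`.
#' @param slice Slice index (1-based); default the mid slice.
#' @param model Optional `voxdose_model` whose body outline (HU > -950) is
#'   drawn as a contour.
#' @return A ggplot.
#' @export
plot_dose_slice <- function(dose, slice = NULL, model = NULL) {
  stopifnot(inherits(dose, "voxdose_dose"))
  d <- dim(dose$dose)
  if (is.null(slice)) slice <- round(d[3] / 2)
  xs <- axis_coords(d[1], dose$spacing[1], dose$origin[1])
  ys <- axis_coords(d[2], dose$spacing[2], dose$origin[2])
  df <- expand.grid(x = xs, y = ys)
  df$dose <- as.numeric(dose$dose[, , slice])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = dose$unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Dose, slice %d (z = %.0f mm)", slice,
                                  dose$origin[3] + (slice - 0.5) * dose$spacing[3])) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    df$body <- as.numeric(model$hu[, , slice] > -950)
    p <- p + ggplot2::geom_contour(
      data = df, ggplot2::aes(z = .data$body), breaks = 0.5,
      colour = "white", linewidth = 0.3, inherit.aes = FALSE,
      mapping = ggplot2::aes(.data$x, .data$y, z = .data$body))
  }
  p
}

#' Plot per-phantom scenario organ doses
#'
#' @param object A `voxdose_scenarios`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voxdose_scenarios
#' @export
autoplot.voxdose_scenarios <- function(object, ...) {
  d <- tidy.voxdose_scenarios(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$organ, .data$dose,
                                  fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Organ dose (per photon-per-mm)",
                  fill = "Scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
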