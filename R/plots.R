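# ggplot2 visualisations for the main result types.

#' Heatmap of per-orientation adsorption energies
#'
#' @param object An `ns_adsorption_map` from [orientation_map()].
#' @param ... Unused.
#' @return A ggplot object: theta-phi heatmap of the mean energies (kT).
#' @export
autoplot.ns_adsorption_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi * 180 / pi,
                                   y = .data$theta * 180 / pi,
                                   fill = .data$E)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "E (kT)") +
    ggplot2::labs(
      x = expression(phi ~ "(deg)"), y = expression(theta ~ "(deg)"),
      title = sprintf("Adsorption map: %s, facet %s",
                      attr(object, "protein_id"), attr(object, "facet"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tabulated surface potential
#'
#' @param object An [pmf_table()] object.
#' @param ... Unused.
#' @return A ggplot object: free energy (kT) against SSD (nm), with the
#'   cutoff marked.
#' @export
autoplot.ns_pmf <- function(object, ...) {
  hh <- seq(object$data$h[1], object$r_c, length.out = 400)
  df <- tibble::tibble(h = hh, energy = surface_pmf_eval(object, hh))
  ggplot2::ggplot(df, ggplot2::aes(.data$h, .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$data, size = 0.6, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$r_c, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "surface separation distance h (nm)",
                  y = "free energy (kT)",
                  title = sprintf("%s on facet %s", object$bead,
                                  object$facet)) +
    ggplot2::theme_minimal()
}

#' Measured vs predicted adsorption energies
#'
#' Scatter of a measured free-energy column against a predicted energy
#' column, annotated with the Pearson correlation.
#'
#' @param data A data frame.
#' @param measured,predicted Column names (strings).
#' @param label Optional column of point labels.
#' @return A ggplot object.
#' @export
plot_affinity_correlation <- function(data, measured = "dG_ads_kJmol",
                                      predicted = "E_ads_B_kJmol",
                                      label = "pdb_id") {
  pr <- pearson_r(data[[measured]], data[[predicted]])
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[measured]],
                                          y = .data[[predicted]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = "measured free energy of adsorption (kJ/mol)",
      y = "predicted adsorption energy (kJ/mol)",
      subtitle = sprintf("r = %.2f, p = %.2g (n = %d)", pr$r, pr$p_value, pr$n)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(label) && label %in% names(data)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data[[label]]),
                                vjust = -0.8, size = 3)
  }
  p
}
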