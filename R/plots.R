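#' @import ggplot2
NULL

#' Plot a fitted parameter map slice
#'
#' @param object A `"dki_maps"` object.
#' @param map Which map to draw: `"d_app"`, `"k_app"`, `"s0"` or `"rss"`.
#' @param slice Axial slice index.
#' @param ... Unused.
#' @return A ggplot raster of the requested map.
#' @method autoplot dki_maps
#' @export
autoplot.dki_maps <- function(object, map = c("d_app", "k_app", "s0", "rss"),
                              slice = 1L, ...) {
  map <- match.arg(map)
  m <- object[[map]][, , slice]
  scale_fct <- if (map == "d_app") 1e3 else 1
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$value <- as.vector(m) * scale_fct
  lab <- switch(map, d_app = "D_app (1e-3 mm²/s)",
                k_app = "K_app", s0 = "S0", rss = "RSS")
  ggplot(df, aes(x = .data$y, y = .data$x, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey20") +
    coord_equal() +
    labs(fill = lab, x = NULL, y = NULL,
         title = sprintf("%s map, slice %d", lab, slice)) +
    theme_minimal()
}

#' Plot a pixel classification map
#'
#' @param object A [classify_pixels()] result.
#' @param ... Unused.
#' @return A ggplot raster with the three tissue classes.
#' @method autoplot pixel_classes
#' @export
autoplot.pixel_classes <- function(object, ...) {
  lab <- object$labels
  df <- tidyr::expand_grid(row = seq_len(nrow(lab)), col = seq_len(ncol(lab)))
  df$class <- factor(as.vector(lab), levels = c(1, 2, 0),
                     labels = c("cellularity", "FSM", "luminal"))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$class)) +
    geom_raster() +
    scale_fill_manual(values = c(cellularity = "#4B2E83", FSM = "#D982B5",
                                 luminal = "white"),
                      na.value = "grey60", drop = FALSE) +
    coord_equal() +
    scale_y_reverse() +
    labs(x = NULL, y = NULL, fill = "class") +
    theme_minimal()
}

#' Plot composition-DKI associations of a cohort
#'
#' Scatter plots of each DKI median against each tissue fraction, split by
#' tissue type — the study's correlation grid in graphical form.
#'
#' @param cohort A cohort tibble (e.g. from [simulate_cohort()] or a
#'   [run_pipeline()] result's `$cohort`).
#' @return A faceted ggplot.
#' @export
plot_cohort_associations <- function(cohort) {
  check_cohort_table(cohort)
  long <- tidyr::pivot_longer(cohort, c("cellularity", "fsm", "luminal"),
                              names_to = "fraction", values_to = "area_fraction")
  long <- tidyr::pivot_longer(long, c("median_d_app", "median_k_app"),
                              names_to = "parameter", values_to = "value")
  ggplot(long, aes(x = .data$area_fraction, y = .data$value,
                   colour = .data$tissue)) +
    geom_point(alpha = 0.7) +
    facet_grid(rows = vars(.data$parameter), cols = vars(.data$fraction),
               scales = "free") +
    labs(x = "fractional area", y = "ROI median",
         colour = "tissue") +
    theme_bw()
}
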