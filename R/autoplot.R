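# ggplot2 autoplot methods for result objects

#' Plot hemispheric land-sink estimates from a two-box inversion
#'
#' Time series of the inverted Northern (and Southern) Hemisphere land
#' sinks, with 1-sigma ribbons where Monte-Carlo uncertainties are
#' available.
#'
#' @param object A `two_box_inversion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.two_box_inversion <- function(object, ...) {
  e <- tidy(object) |>
    tidyr::pivot_longer(
      cols = c("land_n", "land_s"),
      names_to = "hemisphere", values_to = "sink"
    ) |>
    dplyr::mutate(
      sigma = dplyr::if_else(.data$hemisphere == "land_n",
                             .data$land_n_sigma, .data$land_s_sigma),
      hemisphere = dplyr::recode(.data$hemisphere,
                                 land_n = "Northern", land_s = "Southern")
    )
  p <- ggplot2::ggplot(e, ggplot2::aes(.data$year, .data$sink,
                                       colour = .data$hemisphere)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Net land sink (Pg C/yr)",
                  colour = "Hemisphere") +
    ggplot2::theme_minimal()
  if (!all(is.na(e$sigma))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$sink - .data$sigma,
                   ymax = .data$sink + .data$sigma,
                   fill = .data$hemisphere),
      alpha = 0.2, colour = NA
    ) + ggplot2::labs(fill = "Hemisphere")
  }
  p
}

#' Plot a vegetation-carbon change map
#'
#' Raster map of absolute biomass change with masked cells greyed out.
#'
#' @param object A `biomass_change_map` from [relative_change_map()].
#' @param what `"change_abs"` (Mg C/ha) or `"change_pct"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biomass_change_map <- function(object, what = "change_abs", ...) {
  df <- dplyr::mutate(object,
                      shown = ifelse(.data$masked, NA, .data[[what]]))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$shown)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "sienna", mid = "white",
                                  high = "darkgreen", na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "Longitude", y = "Latitude",
      fill = if (what == "change_abs") "Mg C/ha" else "%"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-model scale factors
#'
#' Per-model S values with the ensemble mean and 1-sigma band.
#'
#' @param object A `scale_factor` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scale_factor <- function(object, ...) {
  m <- dplyr::filter(tidy(object), !.data$excluded)
  ggplot2::ggplot(m, ggplot2::aes(.data$model, .data$s)) +
    ggplot2::geom_hline(yintercept = object$mean, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean + c(-1, 1) * object$sd,
                        colour = "steelblue", linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "S = cumulative NBP / ΔC_VEG") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Vector diagram of an O2/CO2 sink partition
#'
#' Draws the fossil, land, and ocean vectors in the (CO2, O2) plane: fossil
#' consumes O2 and adds CO2, the land sink removes CO2 while releasing O2
#' along its oxidative ratio, and the ocean sink removes CO2 at constant
#' O2. The vectors close on the observed atmospheric trend.
#'
#' @param object A `sink_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sink_partition <- function(object, ...) {
  st <- object$inputs$stoich
  f <- object$inputs$fossil
  segs <- tibble::tibble(
    component = c("fossil", "land sink", "ocean sink"),
    x0 = c(0, f, f - object$land),
    y0 = c(0, -st$alpha_f * f,
           -st$alpha_f * f + st$alpha_b * object$land),
    dx = c(f, -object$land, -object$ocean),
    dy = c(-st$alpha_f * f, st$alpha_b * object$land, 0)
  )
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x0 + .data$dx, yend = .data$y0 + .data$dy,
                   colour = .data$component),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.2, "cm"))
    ) +
    ggplot2::labs(x = "CO2 change (Pg C/yr)",
                  y = "O2 change (Pg C-equiv/yr)", colour = NULL) +
    ggplot2::theme_minimal()
}
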