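# broom-style tidiers for the package's fitted/result objects

#' Tidy a two-box inversion
#'
#' @param x A `two_box_inversion` object.
#' @param ... Unused.
#' @return Year-by-year estimates as a tibble (`tidy`), or one-row period
#'   summary with mean hemispheric sinks and cumulative sums (`glance`).
#' @export
tidy.two_box_inversion <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.two_box_inversion
#' @export
glance.two_box_inversion <- function(x, ...) {
  e <- x$estimates
  tibble::tibble(
    n_years = nrow(e),
    mean_land_n = mean(e$land_n),
    mean_land_s = mean(e$land_s),
    cumulative_land_n = sum(e$land_n),
    cumulative_land_s = sum(e$land_s),
    tau = x$params$tau,
    mode = x$mode
  )
}

#' Tidy a scale-factor estimate
#'
#' @param x A `scale_factor` object.
#' @param ... Unused.
#' @return Per-model ratios (`tidy`) or the ensemble mean/sd (`glance`).
#' @export
tidy.scale_factor <- function(x, ...) {
  x$models
}

#' @rdname tidy.scale_factor
#' @export
glance.scale_factor <- function(x, ...) {
  tibble::tibble(
    s_mean = x$mean, s_sd = x$sd,
    n_models = sum(!x$models$excluded),
    n_excluded = sum(x$models$excluded),
    window_start = x$window[1], window_end = x$window[2]
  )
}

#' Tidy an O2/CO2 sink partition
#'
#' @param x A `sink_partition` object.
#' @param ... Unused.
#' @return Component-wise estimates (`tidy`) or a one-row summary
#'   (`glance`).
#' @export
tidy.sink_partition <- function(x, ...) {
  tibble::tibble(
    component = c("land", "ocean"),
    estimate = c(x$land, x$ocean),
    sigma = c(x$land_sigma, x$ocean_sigma)
  )
}

#' @rdname tidy.sink_partition
#' @export
glance.sink_partition <- function(x, ...) {
  tibble::tibble(
    land = x$land, land_sigma = x$land_sigma,
    ocean = x$ocean, ocean_sigma = x$ocean_sigma,
    fossil = x$inputs$fossil, dco2 = x$inputs$dco2,
    scenario = x$scenario %||% "baseline"
  )
}

#' Tidy a budget closure
#'
#' @param x A `budget_closure` object.
#' @param ... Unused.
#' @return The per-term adjustment report (`tidy`) or the before/after
#'   imbalance (`glance`).
#' @export
tidy.budget_closure <- function(x, ...) {
  x$report
}

#' @rdname tidy.budget_closure
#' @export
glance.budget_closure <- function(x, ...) {
  tibble::tibble(imbalance_before = x$imbalance_before,
                 imbalance_after = x$imbalance_after)
}

#' Tidy an ensemble summary
#'
#' @param x An `ensemble_summary` object.
#' @param ... Unused.
#' @return Per-model values (`tidy`) or the mean/sd/bias summary
#'   (`glance`).
#' @export
tidy.ensemble_summary <- function(x, ...) {
  tibble::tibble(model = seq_along(x$values), value = x$values)
}

#' @rdname tidy.ensemble_summary
#' @export
glance.ensemble_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n = x$n,
                 reference = x$reference, bias_pct = x$bias_pct)
}
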