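#' Budget imbalance of a period-mean budget table
#'
#' The imbalance is the amount by which the four budget terms fail to close:
#' fossil - growth - ocean - land (Pg C/yr). A positive imbalance means the
#' stated sources exceed the stated accumulations and sinks.
#'
#' @param budget A budget table from [budget_table()].
#' @return Imbalance in Pg C/yr (single number).
#' @examples
#' budget_imbalance(gcp_budget_2000_2019())   # -0.1
#' budget_imbalance(weak_sink_budget_2000_2019())  # 0.7 before closure
#' @export
budget_imbalance <- function(budget) {
  term_value(budget, "fossil") - term_value(budget, "growth") -
    term_value(budget, "ocean") - term_value(budget, "land")
}

#' Close a budget by scaling its terms
#'
#' Applies multiplicative adjustments to budget terms (uncertainties scale
#' proportionally) and reports the absolute adjustment to each term and the
#' residual imbalance. The atmospheric growth rate is measured precisely, so
#' an adjustment of more than 1% to `growth` triggers a warning.
#'
#' @param budget A budget table.
#' @param fossil,growth,ocean,land Multiplicative scale factors (> 0).
#' @return An object of class `budget_closure`: a list with the adjusted
#'   `budget`, a per-term `report` tibble (multiplier, before, after,
#'   adjustment in Pg C/yr), and the imbalance before and after.
#' @examples
#' cl <- close_budget(gcp_budget_2000_2019(), fossil = 0.94, ocean = 1.08)
#' tidy(cl)
#' glance(cl)
#' @export
close_budget <- function(budget, fossil = 1, growth = 1, ocean = 1, land = 1) {
  mult <- c(fossil = fossil, growth = growth, ocean = ocean, land = land)
  if (any(mult <= 0)) abort("Scale factors must be > 0.")
  if (abs(growth - 1) > 0.01) {
    warn("Adjusting the atmospheric growth rate by more than 1%: this term is measured precisely and should normally be left fixed.")
  }
  before <- budget_imbalance(budget)
  adjusted <- budget |>
    dplyr::mutate(
      multiplier = unname(mult[.data$term]),
      adjustment = .data$mean * (.data$multiplier - 1),
      mean = .data$mean * .data$multiplier,
      sigma = .data$sigma * .data$multiplier
    )
  out_budget <- dplyr::select(adjusted, "term", "mean", "sigma")
  attr(out_budget, "period") <- attr(budget, "period")
  report <- adjusted |>
    dplyr::transmute(
      term = .data$term,
      multiplier = .data$multiplier,
      before = .data$mean / .data$multiplier,
      after = .data$mean,
      adjustment = .data$adjustment
    )
  structure(
    list(budget = out_budget, report = report,
         imbalance_before = before,
         imbalance_after = budget_imbalance(out_budget)),
    class = "budget_closure"
  )
}

#' @export
print.budget_closure <- function(x, ...) {
  cat("Budget closure\n")
  print(x$report)
  cat(sprintf("Imbalance: %.3f -> %.3f Pg C/yr\n",
              x$imbalance_before, x$imbalance_after))
  invisible(x)
}

#' Residual-term uncertainty by quadrature
#'
#' When one budget term is inferred as the residual of the others, its
#' 1-sigma uncertainty is the quadrature sum of the known terms'
#' uncertainties (independence assumed). Used here in reverse to assign an
#' uncertainty to the fossil flux from the growth, ocean, and land terms.
#'
#' @param known_sigmas Numeric vector of 1-sigma uncertainties (Pg C/yr).
#' @param reference_mean Mean of the residual term (Pg C/yr, > 0) used to
#'   express the uncertainty as a percentage.
#' @return A tibble with `sigma` (Pg C/yr) and `percent`.
#' @examples
#' residual_uncertainty(c(0.1, 0.5, 0.7), 8.1)  # ~0.87 Pg C/yr, ~11%
#' @export
residual_uncertainty <- function(known_sigmas, reference_mean) {
  if (length(known_sigmas) < 1) abort("Need at least one uncertainty.")
  if (any(known_sigmas < 0)) abort("Uncertainties must be >= 0.")
  assert_scalar_number(reference_mean, "reference_mean", positive = TRUE)
  s <- quadrature(known_sigmas)
  tibble::tibble(sigma = s, percent = 100 * s / reference_mean)
}

#' Percent difference relative to a reference
#'
#' @param a Value(s) to compare (Pg C/yr or any common unit).
#' @param b Reference value(s); must be nonzero.
#' @return 100 * (a - b) / b, vectorized.
#' @examples
#' percent_difference(2.7, 2.5)  # +8
#' percent_difference(8.1, 8.6)  # -5.8, prints as -6 at table precision
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) abort("Reference value must be nonzero.")
  100 * (a - b) / b
}

#' Calibrate an ocean-sink series to a data-constrained window mean
#'
#' Rescales a whole ocean-sink time series so that its mean over a
#' calibration window matches a data-constrained estimate of anthropogenic
#' carbon uptake for that window (e.g. the 1994-2007 interior-ocean
#' inventory change), optionally after adding a small adjustment for the
#' natural carbon loss component driven by climate warming.
#'
#' @param series Tibble `year,value` (Pg C/yr); a `sigma` column, if
#'   present, is scaled too.
#' @param window Length-2 inclusive year range used for calibration.
#' @param target_mean Data-constrained mean flux over the window (Pg C/yr).
#' @param natural_loss_adjustment Scalar added to `target_mean` (Pg C/yr).
#' @return List with `scale` (single number) and `series` (scaled tibble).
#' @examples
#' s <- tibble::tibble(year = 1990:2010, value = 2.0)
#' calibrate_ocean_scale(s, c(1994, 2007), target_mean = 2.16)$scale  # 1.08
#' @export
calibrate_ocean_scale <- function(series, window, target_mean,
                                  natural_loss_adjustment = 0) {
  assert_columns(series, c("year", "value"), "series")
  if (length(window) != 2) abort("`window` must be a length-2 year range.")
  in_win <- series$year >= min(window) & series$year <= max(window)
  if (!any(in_win)) abort("`window` lies outside the series.")
  wmean <- mean(series$value[in_win])
  if (wmean == 0) abort("Window mean is zero; cannot calibrate.")
  scale <- (target_mean + natural_loss_adjustment) / wmean
  scaled <- dplyr::mutate(series, value = .data$value * scale)
  if ("sigma" %in% names(scaled)) scaled$sigma <- scaled$sigma * abs(scale)
  list(scale = scale, series = scaled)
}

#' Monte-Carlo check of quadrature uncertainty propagation
#'
#' Draws the four budget terms as independent Gaussians and compares the
#' Monte-Carlo standard deviation of the residual (fossil - growth - ocean -
#' land) with the quadrature prediction.
#'
#' @param budget A budget table.
#' @param n Number of draws (>= 1e4).
#' @param seed Integer seed.
#' @return Tibble with `mc_sigma`, `quadrature_sigma`, and
#'   `relative_discrepancy`.
#' @export
mc_propagation_check <- function(budget, n = 1e5, seed = 1) {
  if (n < 1e4) abort("`n` must be at least 1e4 for a stable check.")
  assert_columns(budget, c("term", "mean", "sigma"), "budget")
  quad <- quadrature(budget$sigma)
  set.seed(child_seed(seed, "mc_propagation"))
  draws <- purrr::map(budget$term, function(tm) {
    rnorm(n, term_value(budget, tm), term_value(budget, tm, "sigma"))
  })
  names(draws) <- budget$term
  resid <- draws$fossil - draws$growth - draws$ocean - draws$land
  mc <- sd(resid)
  rel <- if (quad == 0) 0 else abs(mc - quad) / quad
  tibble::tibble(mc_sigma = mc, quadrature_sigma = quad,
                 relative_discrepancy = rel)
}
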