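#' Stoichiometry and molar constants of the atmospheric O2 budget
#'
#' Fossil fuel combustion consumes O2 with an oxidative ratio `alpha_f`
#' (mol O2 per mol C), terrestrial carbon storage releases O2 with ratio
#' `alpha_b`, and the ocean carbon sink is O2-neutral apart from a net
#' outgassing term `z_ocean` (expressed in Pg C-equivalent/yr) driven by
#' warming and stratification. Defaults follow the community-standard
#' O2-based partitioning convention and are fully configurable.
#'
#' @param alpha_f,alpha_b Oxidative ratios (> 0), mol O2 per mol C.
#' @param z_ocean Net ocean O2 outgassing, Pg C-equivalent/yr.
#' @param z_sigma 1-sigma uncertainty on `z_ocean`.
#' @param x_o2 Atmospheric O2 mole fraction.
#' @param m_air Total moles of dry air in the atmosphere.
#' @return A list of class `o2_stoichiometry`.
#' @export
o2_stoichiometry <- function(alpha_f = 1.38, alpha_b = 1.10,
                             z_ocean = 0, z_sigma = 0,
                             x_o2 = 0.20946, m_air = 1.769e20) {
  assert_scalar_number(alpha_f, "alpha_f", positive = TRUE)
  assert_scalar_number(alpha_b, "alpha_b", positive = TRUE)
  assert_scalar_number(z_sigma, "z_sigma", nonneg = TRUE)
  assert_scalar_number(x_o2, "x_o2", positive = TRUE)
  assert_scalar_number(m_air, "m_air", positive = TRUE)
  structure(list(alpha_f = alpha_f, alpha_b = alpha_b,
                 z_ocean = z_ocean, z_sigma = z_sigma,
                 x_o2 = x_o2, m_air = m_air),
            class = "o2_stoichiometry")
}

# Pg C-equivalent corresponding to a 1 per meg change of the O2/N2 ratio
pgc_per_per_meg <- function(stoich) {
  1e-6 * stoich$x_o2 * stoich$m_air * 12e-15
}

#' Convert a per meg O2/N2 rate to molar and carbon-equivalent units
#'
#' A change of 1 per meg is a 1e-6 relative change of the O2/N2 ratio; the
#' corresponding O2 amount is `1e-6 * x_o2 * m_air` moles, and the carbon
#' equivalent uses 12 g C/mol (1 Pg = 1e15 g).
#'
#' @param rate Rate(s) in per meg/yr.
#' @param stoich [o2_stoichiometry()] holding the molar constants.
#' @return Tibble with `mol_o2` (mol/yr) and `pgc_equiv` (Pg C-equiv/yr).
#' @examples
#' per_meg_conversion(1)  # ~3.71e13 mol/yr
#' @export
per_meg_conversion <- function(rate, stoich = o2_stoichiometry()) {
  mol <- rate * 1e-6 * stoich$x_o2 * stoich$m_air
  tibble::tibble(mol_o2 = mol, pgc_equiv = mol * 12e-15)
}

#' Forward atmospheric O2 budget
#'
#' The atmospheric O2 trend is the sum of fossil consumption, biospheric
#' release, and ocean outgassing:
#' `dO2 = -alpha_f * fossil + alpha_b * land_sink + z_ocean`
#' in Pg C-equivalent/yr, also reported in per meg/yr.
#'
#' @param fossil Fossil fuel emissions, Pg C/yr.
#' @param land_sink Net land carbon sink, Pg C/yr (positive = uptake).
#' @param stoich [o2_stoichiometry()].
#' @return Tibble with `do2_pgc` (Pg C-equiv/yr) and `do2_per_meg`
#'   (per meg/yr), vectorized over the inputs.
#' @examples
#' forward_o2_budget(8, 1)  # -9.94 Pg C-equiv/yr with default ratios
#' @export
forward_o2_budget <- function(fossil, land_sink, stoich = o2_stoichiometry()) {
  do2 <- -stoich$alpha_f * fossil + stoich$alpha_b * land_sink + stoich$z_ocean
  tibble::tibble(do2_pgc = do2, do2_per_meg = do2 / pgc_per_per_meg(stoich))
}

#' OLS trend of an annual series
#'
#' Ordinary least-squares slope of annual means against year; the standard
#' unit bridge from raw station records to the budget-level rates consumed
#' by [partition_sinks()].
#'
#' @param data Tibble with a `year` column.
#' @param value Name of the value column.
#' @return Tibble with `slope` (units/yr) and `slope_se`.
#' @export
annual_trend <- function(data, value = "value") {
  assert_columns(data, c("year", value), "data")
  if (nrow(data) < 2) abort("Need at least two years to fit a trend.")
  fit <- lm(data[[value]] ~ data$year)
  slope <- unname(coef(fit)[2])
  n <- nrow(data)
  se <- if (n > 2) {
    sxx <- sum((data$year - mean(data$year))^2)
    sqrt(sum(fit$residuals^2) / (n - 2) / sxx)
  } else {
    NA_real_
  }
  tibble::tibble(slope = slope, slope_se = se)
}

#' Partition land and ocean sinks from O2 and CO2 trends
#'
#' Solves the joint atmospheric O2/CO2 budget for the land sink `B` and
#' ocean sink `O` given the CO2 growth rate, the O2 trend, and fossil
#' emissions:
#' `B = (dO2 + alpha_f * fossil - z_ocean) / alpha_b`,
#' `O = fossil - dCO2 - B`.
#' This is the exact inverse of [forward_o2_budget()] combined with carbon
#' closure, so the land sink carries a leverage `alpha_f / alpha_b > 1` on
#' any fossil-flux bias, and the ocean sink the complement `1 - alpha_f /
#' alpha_b < 0`. Uncertainties come from seeded Monte-Carlo perturbation of
#' fossil, the two trends, and `z_ocean`.
#'
#' @param dco2 Atmospheric CO2 growth rate, Pg C/yr.
#' @param do2 Atmospheric O2 trend, Pg C-equivalent/yr (negative for the
#'   observed decline). Use [per_meg_conversion()] to convert per meg rates.
#' @param fossil Fossil fuel emissions, Pg C/yr.
#' @param stoich [o2_stoichiometry()]; its `z_ocean`/`z_sigma` enter here.
#' @param fossil_sigma,dco2_sigma,do2_sigma 1-sigma uncertainties.
#' @param mc Optional `list(n =, seed =)` for Monte-Carlo uncertainties.
#' @param scenario Optional label stored with the result.
#' @return Object of class `sink_partition` with `land`, `ocean` (Pg C/yr),
#'   their sigmas, and the inputs; `tidy()`/`glance()` methods available.
#' @export
partition_sinks <- function(dco2, do2, fossil, stoich = o2_stoichiometry(),
                            fossil_sigma = 0, dco2_sigma = 0, do2_sigma = 0,
                            mc = NULL, scenario = NULL) {
  if (stoich$alpha_b == 0) abort("`alpha_b` must be nonzero (singular system).")
  solve_once <- function(dco2, do2, fossil, z) {
    b <- (do2 + stoich$alpha_f * fossil - z) / stoich$alpha_b
    list(land = b, ocean = fossil - dco2 - b)
  }
  central <- solve_once(dco2, do2, fossil, stoich$z_ocean)
  land_sigma <- ocean_sigma <- NA_real_
  if (!is.null(mc)) {
    n <- mc$n %||% 2000
    set.seed(child_seed(mc$seed %||% 1, "partition_sinks"))
    draws <- purrr::map(seq_len(n), function(i) {
      solve_once(dco2 + rnorm(1, 0, dco2_sigma),
                 do2 + rnorm(1, 0, do2_sigma),
                 fossil + rnorm(1, 0, fossil_sigma),
                 stoich$z_ocean + rnorm(1, 0, stoich$z_sigma))
    })
    land_sigma <- sd(purrr::map_dbl(draws, "land"))
    ocean_sigma <- sd(purrr::map_dbl(draws, "ocean"))
  }
  structure(
    list(land = central$land, ocean = central$ocean,
         land_sigma = land_sigma, ocean_sigma = ocean_sigma,
         inputs = list(dco2 = dco2, do2 = do2, fossil = fossil,
                       stoich = stoich),
         scenario = scenario),
    class = "sink_partition"
  )
}

#' @export
print.sink_partition <- function(x, ...) {
  cat(sprintf("O2/CO2 sink partition%s\n",
              if (is.null(x$scenario)) "" else paste0(" (", x$scenario, ")")))
  cat(sprintf("  land sink:  %.2f Pg C/yr\n", x$land))
  cat(sprintf("  ocean sink: %.2f Pg C/yr\n", x$ocean))
  invisible(x)
}
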