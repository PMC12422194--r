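#' Fuse two independent estimates by inverse-variance weighting
#'
#' Combines two estimates of the same quantity (e.g. vegetation carbon
#' change from two satellite biomass products) with inverse-variance
#' weights, the minimum-variance combination under independent Gaussian
#' errors: fused variance `1/(1/sa^2 + 1/sb^2)`. Vectorized, so it applies
#' equally to scalars and to aligned grid cells; where one input is missing
#' (NA) the other passes through.
#'
#' @param value_a,sigma_a First estimate and its 1-sigma.
#' @param value_b,sigma_b Second estimate and its 1-sigma.
#' @return Tibble with `value` and `sigma`.
#' @examples
#' fuse_products(8, 4, 12, 4)  # 10 +/- 2.83
#' @export
fuse_products <- function(value_a, sigma_a, value_b, sigma_b) {
  if (any(c(sigma_a, sigma_b) < 0, na.rm = TRUE)) {
    abort("Uncertainties must be >= 0.")
  }
  n <- max(length(value_a), length(value_b))
  value_a <- rep_len(value_a, n); sigma_a <- rep_len(sigma_a, n)
  value_b <- rep_len(value_b, n); sigma_b <- rep_len(sigma_b, n)
  miss_a <- is.na(value_a); miss_b <- is.na(value_b)
  if (any(miss_a & miss_b)) abort("Both inputs missing for some elements.")
  zero_conflict <- !miss_a & !miss_b & sigma_a == 0 & sigma_b == 0 &
    value_a != value_b
  if (any(zero_conflict)) {
    abort("Conflicting values with zero variance cannot be fused.")
  }
  wa <- 1 / sigma_a^2
  wb <- 1 / sigma_b^2
  value <- (wa * value_a + wb * value_b) / (wa + wb)
  sigma <- sqrt(1 / (wa + wb))
  # exact (zero-variance) inputs dominate the weighted mean
  a_exact <- !miss_a & sigma_a == 0
  b_exact <- !miss_b & sigma_b == 0
  value[a_exact] <- value_a[a_exact]
  sigma[a_exact] <- 0
  value[b_exact] <- value_b[b_exact]
  sigma[b_exact] <- 0
  value[miss_a] <- value_b[miss_a]; sigma[miss_a] <- sigma_b[miss_a]
  value[miss_b] <- value_a[miss_b]; sigma[miss_b] <- sigma_a[miss_b]
  tibble::tibble(value = value, sigma = sigma)
}

#' Ensemble scale factor from vegetation change to total ecosystem change
#'
#' For each ensemble member, the scale factor is the ratio of total
#' ecosystem carbon accumulation (the window integral of net biome
#' production, NBP) to the change in the living-vegetation stock over the
#' same window: `S = sum(NBP) / (cVeg(end) - cVeg(start))`. Annual stocks
#' are treated as end-of-year snapshots, so the integral runs over
#' `(start, end]`. The ensemble S is the arithmetic mean across members,
#' with an n-1 standard deviation. Members with `|dCVeg|` below
#' `min_delta_cveg` are excluded with a warning rather than contributing
#' unstable ratios.
#'
#' @param members Long tibble `model, year, nbp, cveg` (Pg C/yr and Pg C).
#' @param window Length-2 inclusive year range.
#' @param min_delta_cveg Exclusion threshold for near-zero vegetation change
#'   (Pg C).
#' @return Object of class `scale_factor` with per-model values and the
#'   ensemble mean and sd; `tidy()`/`glance()` methods available.
#' @export
compute_scale_factor <- function(members, window, min_delta_cveg = 0.1) {
  assert_columns(members, c("model", "year", "nbp", "cveg"), "members")
  y0 <- min(window); y1 <- max(window)
  if (y1 <= y0) abort("`window` must span at least two years.")
  per_model <- members |>
    dplyr::filter(.data$year >= y0, .data$year <= y1) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      cum_nbp = sum(.data$nbp[.data$year > y0]),
      delta_cveg = .data$cveg[.data$year == y1] - .data$cveg[.data$year == y0],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      excluded = abs(.data$delta_cveg) < min_delta_cveg,
      s = dplyr::if_else(.data$excluded, NA_real_,
                         .data$cum_nbp / .data$delta_cveg)
    )
  if (any(per_model$excluded)) {
    warn(sprintf(
      "Excluding %d member(s) with |dCVeg| < %g Pg C from the scale factor: %s",
      sum(per_model$excluded), min_delta_cveg,
      paste(per_model$model[per_model$excluded], collapse = ", ")
    ))
  }
  kept <- per_model$s[!per_model$excluded]
  if (length(kept) == 0) abort("No usable ensemble members for S.")
  structure(
    list(models = per_model,
         mean = mean(kept),
         sd = if (length(kept) > 1) sd(kept) else 0,
         window = c(y0, y1)),
    class = "scale_factor"
  )
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("Scale factor S = %.2f +/- %.2f (%d models, %d-%d)\n",
              x$mean, x$sd, sum(!x$models$excluded),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Scale a vegetation carbon change to whole-ecosystem carbon change
#'
#' Multiplies a vegetation stock change by the ensemble scale factor,
#' `dCLand = S * dCVeg`, with the exact product variance for independent
#' inputs: `S^2 sv^2 + V^2 ss^2 + ss^2 sv^2` (the cross term is retained).
#'
#' @param delta_cveg Vegetation carbon change, Pg C.
#' @param sigma_cveg Its 1-sigma, Pg C.
#' @param s A [compute_scale_factor()] result, or a numeric mean.
#' @param s_sigma 1-sigma of S when `s` is numeric.
#' @return Tibble with `delta_cland`, `delta_cland_sigma` and the inputs.
#' @examples
#' scale_to_land(10.1, 7.0, 1.6, 0.6)  # 16.16 +/- 13.41 Pg C
#' @export
scale_to_land <- function(delta_cveg, sigma_cveg, s, s_sigma = 0) {
  if (inherits(s, "scale_factor")) {
    s_sigma <- s$sd
    s <- s$mean
  }
  assert_scalar_number(sigma_cveg, "sigma_cveg", nonneg = TRUE)
  assert_scalar_number(s_sigma, "s_sigma", nonneg = TRUE)
  variance <- s^2 * sigma_cveg^2 + delta_cveg^2 * s_sigma^2 +
    s_sigma^2 * sigma_cveg^2
  tibble::tibble(
    delta_cland = s * delta_cveg,
    delta_cland_sigma = sqrt(variance),
    delta_cveg = delta_cveg, delta_cveg_sigma = sigma_cveg,
    s = s, s_sigma = s_sigma
  )
}

#' Combine ecosystem pool changes into a total land carbon change
#'
#' Total land carbon change decomposes into living vegetation, litter (fine
#' and coarse, including dead wood), and soil organic matter:
#' `dCLand = dCVeg + dCLitter + dCSoil`, with quadrature uncertainty.
#'
#' @param delta_cveg,delta_clitter,delta_csoil Pool changes, Pg C.
#' @param sigma_cveg,sigma_clitter,sigma_csoil 1-sigma uncertainties.
#' @return One-row tibble with the pools and `delta_cland` (+ sigma).
#' @export
combine_pools <- function(delta_cveg, delta_clitter = 0, delta_csoil = 0,
                          sigma_cveg = 0, sigma_clitter = 0, sigma_csoil = 0) {
  tibble::tibble(
    delta_cveg = delta_cveg, delta_clitter = delta_clitter,
    delta_csoil = delta_csoil,
    delta_cland = delta_cveg + delta_clitter + delta_csoil,
    delta_cland_sigma = quadrature(sigma_cveg, sigma_clitter, sigma_csoil)
  )
}

#' Convert a stock change over an interval to an annual flux
#'
#' Divides a carbon stock change and its uncertainty by the interval length
#' in years. Named-year intervals follow the midpoint-to-midpoint
#' convention: midpoint of 2000 to midpoint of 2019 is 19.0 years.
#'
#' @param value Stock change, Pg C.
#' @param sigma Its 1-sigma, Pg C.
#' @param interval Interval length in years (> 0).
#' @return Tibble with `flux` and `flux_sigma` in Pg C/yr.
#' @examples
#' stock_to_flux(16.0, 13.1, 19)  # 0.84 +/- 0.69 Pg C/yr
#' @export
stock_to_flux <- function(value, sigma = 0, interval) {
  assert_scalar_number(interval, "interval", positive = TRUE)
  tibble::tibble(flux = value / interval, flux_sigma = sigma / interval)
}

#' Relative increase of a stock implied by a cumulative flux
#'
#' Given the cumulative carbon accumulated over a period and the stock at
#' the end of the period, infers the starting stock by subtraction and
#' returns the percent growth the accumulation would represent if it all
#' resided in that pool: `100 * cumulative / (end_stock - cumulative)`.
#'
#' @param cumulative Accumulated carbon over the period, Pg C.
#' @param end_stock Stock at the end of the period, Pg C; must exceed
#'   `cumulative`.
#' @return Percent increase (single number).
#' @examples
#' relative_stock_increase(57, 411)  # ~16% global
#' relative_stock_increase(85, 262)  # ~48% Northern Hemisphere
#' @export
relative_stock_increase <- function(cumulative, end_stock) {
  if (end_stock <= cumulative) {
    abort("`end_stock` must exceed `cumulative` (implied start stock <= 0).")
  }
  100 * cumulative / (end_stock - cumulative)
}

#' Absolute and relative vegetation-carbon change maps
#'
#' Cell-by-cell change between two biomass epochs: the absolute change in
#' Mg C/ha over the interval and the percent change relative to the early
#' epoch. Cells whose early-epoch stock is below `mask_threshold` are
#' flagged masked (relative changes over near-zero stocks are meaningless).
#'
#' @param early,late Biomass grids sharing lat/lon axes (tibbles with
#'   `lat, lon, cveg, area_ha`; see [sim_biomass_grids()]).
#' @param mask_threshold Mask cells with early stock below this (Mg C/ha).
#' @return Tibble `lat, lon, early, late, change_abs, change_pct, masked,
#'   area_ha` of class `biomass_change_map`.
#' @export
relative_change_map <- function(early, late, mask_threshold = 1) {
  assert_columns(early, c("lat", "lon", "cveg", "area_ha"), "early")
  assert_columns(late, c("lat", "lon", "cveg"), "late")
  e <- dplyr::arrange(early, .data$lat, .data$lon)
  l <- dplyr::arrange(late, .data$lat, .data$lon)
  if (nrow(e) != nrow(l) ||
      !isTRUE(all.equal(e$lat, l$lat)) || !isTRUE(all.equal(e$lon, l$lon))) {
    abort("`early` and `late` must share identical lat/lon axes.")
  }
  out <- tibble::tibble(
    lat = e$lat, lon = e$lon,
    early = e$cveg, late = l$cveg,
    change_abs = l$cveg - e$cveg,
    change_pct = ifelse(e$cveg > 0, 100 * (l$cveg - e$cveg) / e$cveg,
                        NA_real_),
    masked = e$cveg < mask_threshold,
    area_ha = e$area_ha
  )
  class(out) <- c("biomass_change_map", class(out))
  out
}

#' Area-weighted global totals of a biomass grid or change map
#'
#' Sums stock densities (Mg C/ha) times cell areas (ha) and converts to
#' Pg C (1 Pg C = 1e9 Mg C).
#'
#' @param grid A biomass grid tibble (`cveg`) or change map (`change_abs`).
#' @return Total in Pg C.
#' @export
grid_total_pgc <- function(grid) {
  col <- if ("change_abs" %in% names(grid)) "change_abs" else "cveg"
  assert_columns(grid, c(col, "area_ha"), "grid")
  sum(grid[[col]] * grid$area_ha) * 1e-9
}
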