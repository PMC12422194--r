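#' Transport parameters of the two-box atmosphere
#'
#' The two-box model divides the atmosphere into Northern and Southern
#' Hemisphere boxes that exchange air with an e-folding timescale `tau`.
#' `kappa_global` converts a global-mean mixing ratio change (ppm) into an
#' atmospheric carbon mass change (Pg C); each hemispheric box holds half
#' the atmosphere, so `kappa_hemisphere = kappa_global / 2`.
#'
#' @param tau Interhemispheric exchange time in years (> 0).
#' @param kappa_global Pg C per ppm for the whole atmosphere (> 0).
#' @return A list of class `transport_params`.
#' @export
transport_params <- function(tau = 1.3, kappa_global = 2.124) {
  assert_scalar_number(tau, "tau", positive = TRUE)
  assert_scalar_number(kappa_global, "kappa_global", positive = TRUE)
  structure(list(tau = tau, kappa_global = kappa_global,
                 kappa_hemisphere = kappa_global / 2),
            class = "transport_params")
}

#' Split global budget terms into hemispheric components
#'
#' Distributes the fossil and ocean terms of a year-indexed budget between
#' hemispheres using fixed fractions. Fossil emissions are concentrated in
#' the Northern Hemisphere; the anthropogenic ocean sink is somewhat larger
#' in the Southern Hemisphere, so its northern fraction is below one half by
#' default. Components sum to the global term exactly, each year.
#'
#' @param budget Year-indexed tibble with columns `year`, `fossil`, `ocean`
#'   (and optionally `fossil_sigma`, `ocean_sigma`).
#' @param ff_north_fraction,ocean_north_fraction Fractions in \[0, 1\] of the
#'   global fossil and ocean terms assigned to the Northern Hemisphere.
#' @return Tibble `year, fossil_n, fossil_s, ocean_n, ocean_s` plus split
#'   sigma columns when available.
#' @examples
#' b <- tibble::tibble(year = 2000, fossil = 8, ocean = 2.3)
#' split_hemispheres(b, 0.94, 0.45)
#' @export
split_hemispheres <- function(budget, ff_north_fraction = 0.94,
                              ocean_north_fraction = 0.45) {
  assert_columns(budget, c("year", "fossil", "ocean"), "budget")
  for (f in c(ff_north_fraction, ocean_north_fraction)) {
    if (!is.finite(f) || f < 0 || f > 1) abort("Fractions must lie in [0, 1].")
  }
  out <- tibble::tibble(
    year = budget$year,
    fossil_n = budget$fossil * ff_north_fraction,
    fossil_s = budget$fossil * (1 - ff_north_fraction),
    ocean_n = budget$ocean * ocean_north_fraction,
    ocean_s = budget$ocean * (1 - ocean_north_fraction)
  )
  if ("fossil_sigma" %in% names(budget)) {
    out$fossil_n_sigma <- budget$fossil_sigma * ff_north_fraction
    out$fossil_s_sigma <- budget$fossil_sigma * (1 - ff_north_fraction)
  }
  if ("ocean_sigma" %in% names(budget)) {
    out$ocean_n_sigma <- budget$ocean_sigma * ocean_north_fraction
    out$ocean_s_sigma <- budget$ocean_sigma * (1 - ocean_north_fraction)
  }
  out
}

check_hemi <- function(hemi) {
  assert_columns(hemi, c("year", "fossil_n", "fossil_s", "ocean_n", "ocean_s"),
                 "hemi_fluxes")
  if (is.unsorted(hemi$year, strictly = TRUE)) {
    abort("Years must be strictly increasing.")
  }
  invisible(hemi)
}

#' Forward two-box interhemispheric CO2 model
#'
#' Steps hemispheric annual-mean CO2 forward with an explicit annual scheme:
#' for the northern box,
#' `kappa_h * (C_N(t+1) - C_N(t)) = E_N - O_N - B_N - kappa_h * (C_N - C_S) / tau`,
#' and mirrored for the south with the transport sign flipped. Fluxes for
#' years y1..yT produce concentrations for years y1..y(T+1); annual means are
#' bookkept at the start-of-year state, so the scheme is exactly invertible
#' by [invert_two_box()]. Total atmospheric mass change equals total net
#' flux exactly (the transport terms cancel).
#'
#' @param hemi Hemispheric flux tibble from [split_hemispheres()] (Pg C/yr).
#' @param land Tibble `year, land_n, land_s`: hemispheric net land sinks
#'   (Pg C/yr, positive = uptake), same years as `hemi`.
#' @param init Named numeric `c(north=, south=)` initial annual-mean CO2 (ppm).
#' @param params [transport_params()].
#' @return Tibble `year, co2_n, co2_s` with one more row than `hemi`.
#' @export
forward_two_box <- function(hemi, land, init = c(north = 370, south = 368),
                            params = transport_params()) {
  check_hemi(hemi)
  assert_columns(land, c("year", "land_n", "land_s"), "land")
  if (!identical(as.integer(hemi$year), as.integer(land$year))) {
    abort("`hemi` and `land` must cover the same years.")
  }
  kh <- params$kappa_hemisphere
  tau <- params$tau
  n <- nrow(hemi)
  cn <- cs <- numeric(n + 1)
  cn[1] <- init[["north"]]
  cs[1] <- init[["south"]]
  for (t in seq_len(n)) {
    grad <- cn[t] - cs[t]
    cn[t + 1] <- cn[t] +
      (hemi$fossil_n[t] - hemi$ocean_n[t] - land$land_n[t]) / kh - grad / tau
    cs[t + 1] <- cs[t] +
      (hemi$fossil_s[t] - hemi$ocean_s[t] - land$land_s[t]) / kh + grad / tau
  }
  tibble::tibble(year = c(hemi$year, max(hemi$year) + 1), co2_n = cn, co2_s = cs)
}

#' Invert the two-box model for hemispheric land sinks
#'
#' Recovers the Northern Hemisphere net land sink from the hemispheric CO2
#' records and prescribed fossil and ocean fluxes, using the same discrete
#' scheme as [forward_two_box()]:
#' `B_N(t) = E_N - O_N - kappa_h * dC_N(t) - kappa_h * (C_N - C_S) / tau`.
#' In constrained mode (the default when `global_land` is supplied) the
#' southern sink is the residual `B_S = global_land - B_N`, mirroring how a
#' consensus global land sink is allocated; otherwise `B_S` comes from the
#' southern box budget. 1-sigma uncertainties are estimated by seeded
#' Monte-Carlo perturbation of the concentration records (via `obs_sigma`),
#' the flux sigma columns of `hemi`, and the `sigma` column of `global_land`.
#'
#' @param stations Tibble `year, co2_n, co2_s` (annual-mean ppm) covering the
#'   flux years plus one trailing year.
#' @param hemi Hemispheric flux tibble (see [split_hemispheres()]).
#' @param global_land Optional tibble `year, value` (+ optional `sigma`)
#'   giving the global net land sink used to constrain `B_S`.
#' @param params [transport_params()].
#' @param obs_sigma Observation noise on annual-mean CO2 (ppm), used in the
#'   Monte-Carlo step.
#' @param mc Optional list `list(n =, seed =)` activating Monte-Carlo
#'   uncertainties; `keep_draws = TRUE` retains the draw matrix of `B_N`.
#' @return Object of class `two_box_inversion`; `tidy()` gives the
#'   year-by-year estimates, `glance()` the period means.
#' @export
invert_two_box <- function(stations, hemi, global_land = NULL,
                           params = transport_params(), obs_sigma = 0,
                           mc = NULL) {
  check_hemi(hemi)
  assert_columns(stations, c("year", "co2_n", "co2_s"), "stations")
  need_years <- c(hemi$year, max(hemi$year) + 1)
  if (!all(need_years %in% stations$year)) {
    abort("`stations` must cover every flux year plus one trailing year.")
  }
  if (nrow(hemi) < 1) abort("Need at least one flux year.")
  st <- stations[match(need_years, stations$year), ]
  constrained <- !is.null(global_land)
  gl <- NULL
  if (constrained) {
    assert_columns(global_land, c("year", "value"), "global_land")
    if (!all(hemi$year %in% global_land$year)) {
      abort("`global_land` must cover the flux years.")
    }
    gl <- global_land[match(hemi$year, global_land$year), ]
  }

  solve_once <- function(cn, cs, fossil_n, ocean_n, fossil_s, ocean_s,
                         land_global) {
    kh <- params$kappa_hemisphere
    n <- nrow(hemi)
    idx <- seq_len(n)
    grad <- cn[idx] - cs[idx]
    bn <- fossil_n - ocean_n - kh * diff(cn) - kh * grad / params$tau
    bs <- if (constrained) {
      land_global - bn
    } else {
      fossil_s - ocean_s - kh * diff(cs) + kh * grad / params$tau
    }
    list(bn = bn, bs = bs)
  }

  central <- solve_once(st$co2_n, st$co2_s, hemi$fossil_n, hemi$ocean_n,
                        hemi$fossil_s, hemi$ocean_s,
                        if (constrained) gl$value else NULL)

  bn_sigma <- bs_sigma <- rep(NA_real_, nrow(hemi))
  draws_bn <- NULL
  if (!is.null(mc)) {
    n_mc <- mc$n %||% 2000
    set.seed(child_seed(mc$seed %||% 1, "invert_two_box"))
    ny <- nrow(hemi)
    sig <- function(col) if (col %in% names(hemi)) hemi[[col]] else 0
    gl_sigma <- if (constrained && "sigma" %in% names(gl)) gl$sigma else 0
    draws <- purrr::map(seq_len(n_mc), function(i) {
      solve_once(
        st$co2_n + rnorm(ny + 1, 0, obs_sigma),
        st$co2_s + rnorm(ny + 1, 0, obs_sigma),
        hemi$fossil_n + rnorm(ny, 0, sig("fossil_n_sigma")),
        hemi$ocean_n + rnorm(ny, 0, sig("ocean_n_sigma")),
        hemi$fossil_s + rnorm(ny, 0, sig("fossil_s_sigma")),
        hemi$ocean_s + rnorm(ny, 0, sig("ocean_s_sigma")),
        if (constrained) gl$value + rnorm(ny, 0, gl_sigma) else NULL
      )
    })
    bn_mat <- do.call(rbind, purrr::map(draws, "bn"))
    bs_mat <- do.call(rbind, purrr::map(draws, "bs"))
    bn_sigma <- apply(bn_mat, 2, sd)
    bs_sigma <- apply(bs_mat, 2, sd)
    if (isTRUE(mc$keep_draws)) draws_bn <- bn_mat
  }

  estimates <- tibble::tibble(
    year = hemi$year,
    land_n = central$bn, land_n_sigma = bn_sigma,
    land_s = central$bs, land_s_sigma = bs_sigma
  )
  structure(
    list(estimates = estimates, params = params,
         mode = if (constrained) "constrained" else "unconstrained",
         mc = mc, draws_bn = draws_bn),
    class = "two_box_inversion"
  )
}

#' @export
print.two_box_inversion <- function(x, ...) {
  cat(sprintf("Two-box inversion (%s mode, tau = %.2f yr)\n",
              x$mode, x$params$tau))
  cat(sprintf("Mean NH land sink: %.2f Pg C/yr over %d years\n",
              mean(x$estimates$land_n), nrow(x$estimates)))
  invisible(x)
}

#' Apply a fossil/ocean scenario to budget inputs
#'
#' Scales every fossil term by `ff_scale` and every ocean term by
#' `ocean_scale` (uncertainties proportionally), leaving other terms
#' untouched. Works on hemispheric flux tibbles, year-indexed budget
#' tibbles, and period-mean budget tables, so the same scenario can drive a
#' re-inversion, an O2 re-partitioning, and a ledger closure. The canonical
#' weak-sink scenario is `ff_scale = 0.94, ocean_scale = 1.08`.
#'
#' @param x Tibble with fossil/ocean columns, or a `term,mean,sigma` budget
#'   table.
#' @param ff_scale,ocean_scale Positive multiplicative factors.
#' @return Adjusted object of the same shape.
#' @export
apply_scenario <- function(x, ff_scale = 1, ocean_scale = 1) {
  assert_scalar_number(ff_scale, "ff_scale", positive = TRUE)
  assert_scalar_number(ocean_scale, "ocean_scale", positive = TRUE)
  if (all(c("term", "mean") %in% names(x))) {
    i_f <- x$term == "fossil"
    i_o <- x$term == "ocean"
    x$mean[i_f] <- x$mean[i_f] * ff_scale
    x$mean[i_o] <- x$mean[i_o] * ocean_scale
    if ("sigma" %in% names(x)) {
      x$sigma[i_f] <- x$sigma[i_f] * ff_scale
      x$sigma[i_o] <- x$sigma[i_o] * ocean_scale
    }
    return(x)
  }
  for (col in grep("^fossil", names(x), value = TRUE)) {
    x[[col]] <- x[[col]] * ff_scale
  }
  for (col in grep("^ocean", names(x), value = TRUE)) {
    x[[col]] <- x[[col]] * ocean_scale
  }
  x
}

#' Aggregate a year-indexed flux series
#'
#' @param data Tibble with a `year` column.
#' @param value Column to aggregate (tidy-select, default `value`).
#' @param mode `"cumulative"` (running integral, Pg C), `"decadal_mean"`
#'   (means over calendar decades), or `"period_mean"` (scalar mean over
#'   `window`).
#' @param window Optional inclusive year range; required subset of the data.
#' @return A tibble (`cumulative`, `decadal_mean`) or single number
#'   (`period_mean`).
#' @export
aggregate_series <- function(data, value = "value",
                             mode = c("cumulative", "decadal_mean",
                                      "period_mean"),
                             window = NULL) {
  mode <- match.arg(mode)
  assert_columns(data, c("year", value), "data")
  if (!is.null(window)) {
    data <- dplyr::filter(data, .data$year >= min(window),
                          .data$year <= max(window))
    if (nrow(data) == 0) abort("`window` selects no years.")
  }
  v <- data[[value]]
  switch(mode,
    cumulative = tibble::tibble(year = data$year, cumulative = cumsum(v)),
    decadal_mean = data |>
      dplyr::mutate(decade = 10 * (.data$year %/% 10)) |>
      dplyr::summarise(mean = mean(.data[[value]]), .by = "decade"),
    period_mean = mean(v)
  )
}
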