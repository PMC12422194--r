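#' Simulate a closed annual carbon budget
#'
#' Generates a year-indexed global budget in which fossil emissions follow
#' an exponential trend, the ocean sink tracks a fixed fraction of fossil
#' emissions, and the land sink follows a prescribed "true" trajectory.
#' Interannual Gaussian noise is added to the ocean and growth terms, and
#' the stored land sink is the budget residual — mirroring how the
#' consensus budget is built — so closure holds exactly by construction:
#' `fossil = growth + ocean + land + imbalance` with `imbalance = 0`.
#' The trajectory actually used for the land term is attached as ground
#' truth.
#'
#' @param years Inclusive integer year range (length >= 2).
#' @param ff_start Fossil emissions in the first year, Pg C/yr.
#' @param ff_growth Fractional growth rate of fossil emissions per year.
#' @param ocean_fraction Ocean sink as a fraction of fossil emissions.
#' @param land_sink_true True land sink trajectory, Pg C/yr (recycled);
#'   default is a weak-sink ramp from 0.5 to 1.1 Pg C/yr.
#' @param noise_sd Named vector of interannual noise standard deviations
#'   for the `growth` and `ocean` terms, Pg C/yr.
#' @param sigma Named per-term 1-sigma uncertainties attached to the table.
#' @param seed Integer seed (all randomness is child-seeded from it).
#' @return Tibble `year, fossil, growth, ocean, land, imbalance` plus
#'   per-term sigma columns, with a `truth` attribute carrying
#'   `land_sink_true`.
#' @export
sim_budget_series <- function(years = 2000:2019,
                              ff_start = 7.8, ff_growth = 0.02,
                              ocean_fraction = 0.29,
                              land_sink_true = NULL,
                              noise_sd = c(growth = 0.3, ocean = 0.15),
                              sigma = c(fossil = 0.4, growth = 0.1,
                                        ocean = 0.4, land = 0.6),
                              seed = 1) {
  if (length(years) < 2) abort("`years` must span at least two years.")
  if (any(noise_sd < 0) || any(sigma < 0)) abort("All sd must be >= 0.")
  n <- length(years)
  land_true <- rep_len(land_sink_true %||%
                         seq(0.5, 1.1, length.out = n), n)
  fossil <- ff_start * (1 + ff_growth)^(seq_len(n) - 1)
  set.seed(child_seed(seed, "budget"))
  ocean <- ocean_fraction * fossil + rnorm(n, 0, noise_sd[["ocean"]])
  growth <- fossil - ocean - land_true + rnorm(n, 0, noise_sd[["growth"]])
  land <- fossil - growth - ocean  # residual term, exact closure
  out <- tibble::tibble(
    year = as.integer(years),
    fossil = fossil, growth = growth, ocean = ocean, land = land,
    imbalance = fossil - growth - ocean - land,
    fossil_sigma = sigma[["fossil"]], growth_sigma = sigma[["growth"]],
    ocean_sigma = sigma[["ocean"]], land_sigma = sigma[["land"]]
  )
  attr(out, "truth") <- list(land_sink_true = land_true)
  out
}

#' Simulate hemispheric CO2 station records from known fluxes
#'
#' Runs the forward two-box model over the prescribed hemispheric fossil
#' and ocean fluxes and "true" hemispheric land sinks, then adds seeded
#' Gaussian observation noise to the annual means. The noise-free records
#' are exactly the forward-model trajectories, so [invert_two_box()]
#' recovers the truth to arithmetic tolerance when `obs_noise_sd = 0`.
#'
#' @param hemi Hemispheric flux tibble from [split_hemispheres()].
#' @param land_truth Tibble `year, land_n, land_s`: true hemispheric land
#'   sinks, Pg C/yr.
#' @param params [transport_params()].
#' @param init Initial annual-mean CO2, `c(north=, south=)` ppm.
#' @param obs_noise_sd Observation noise on annual means, ppm.
#' @param seed Integer seed.
#' @return List with `stations` (tibble `year, co2_n, co2_s`), `clean`
#'   (noise-free records), and `truth` (the land trajectory).
#' @export
sim_station_records <- function(hemi, land_truth,
                                params = transport_params(),
                                init = c(north = 370, south = 368),
                                obs_noise_sd = 0, seed = 1) {
  if (!identical(as.integer(hemi$year), as.integer(land_truth$year))) {
    abort("`hemi` and `land_truth` must cover the same years.")
  }
  clean <- forward_two_box(hemi, land_truth, init = init, params = params)
  set.seed(child_seed(seed, "stations"))
  noisy <- clean
  noisy$co2_n <- clean$co2_n + rnorm(nrow(clean), 0, obs_noise_sd)
  noisy$co2_s <- clean$co2_s + rnorm(nrow(clean), 0, obs_noise_sd)
  list(stations = noisy, clean = clean, truth = land_truth)
}

#' Simulate an atmospheric O2/N2 record from a known O2 budget
#'
#' Integrates the forward O2 budget for prescribed fossil emissions and a
#' true land sink: the per meg series declines at the rate implied by
#' `-alpha_f * fossil + alpha_b * B + z_ocean`, starting from `o2_init`.
#' With constant fluxes the series is exactly linear, so an OLS trend plus
#' [partition_sinks()] recovers the true (B, O) pair exactly in noise-free
#' mode.
#'
#' @param years Integer years.
#' @param fossil Fossil emissions, Pg C/yr (recycled over years).
#' @param land_sink_true True land sink B, Pg C/yr (recycled).
#' @param stoich [o2_stoichiometry()].
#' @param noise_sd Observation noise, per meg.
#' @param o2_init Initial O2/N2 value, per meg.
#' @param seed Integer seed.
#' @return List with `o2` (tibble `year, per_meg, sigma`) and `truth`
#'   (true annual B and implied ocean sink requires the CO2 budget).
#' @export
sim_o2_records <- function(years, fossil, land_sink_true,
                           stoich = o2_stoichiometry(),
                           noise_sd = 0, o2_init = 0, seed = 1) {
  n <- length(years)
  fossil <- rep_len(fossil, n)
  b <- rep_len(land_sink_true, n)
  rate <- forward_o2_budget(fossil, b, stoich)$do2_per_meg
  per_meg <- o2_init + c(0, cumsum(rate[-n]))
  set.seed(child_seed(seed, "o2"))
  out <- tibble::tibble(
    year = as.integer(years),
    per_meg = per_meg + rnorm(n, 0, noise_sd),
    sigma = noise_sd
  )
  list(o2 = out, truth = list(land_sink_true = b, rate_per_meg = rate))
}

#' Simulate a CMIP-style ensemble with known scale factors
#'
#' Each member carries annual NBP, the vegetation stock cVeg, and GPP/NPP.
#' The stock is built so that, in noise-free mode, the window integral of
#' NBP equals exactly `s_true` times the vegetation stock change — the
#' quantity [compute_scale_factor()] estimates. Reported NBP adds
#' independent interannual noise on top of the stock-consistent series, so
#' noisy recovery of S is unbiased. GPP grows geometrically and NPP is
#' `cue0 * GPP`, giving a constant carbon-use efficiency.
#'
#' @param years Integer years.
#' @param n_models Number of members (>= 1).
#' @param s_true Per-model true scale factors (recycled); defaults to a
#'   spread with mean 1.6 and sd 0.6, floored at 1 (detrital pools
#'   accumulate).
#' @param nbp_mean Per-model mean NBP, Pg C/yr (recycled); default draws
#'   from N(1.2, 0.6).
#' @param cveg0 Per-model initial vegetation stock, Pg C (recycled);
#'   default draws from N(478, 86).
#' @param gpp0 Initial GPP, Pg C/yr; grows at `gpp_growth` per year.
#' @param gpp_growth Fractional GPP growth per year.
#' @param cue0 Carbon-use efficiency NPP/GPP.
#' @param noise_sd Interannual noise on reported NBP, Pg C/yr.
#' @param n_cells If > 0, also generate per-model pseudo-grid cells with
#'   `delta_cveg` and `cum_nbp = s_true * delta_cveg` (plus noise) for
#'   within-model spatial diagnostics.
#' @param seed Integer seed.
#' @return List with `members` (tibble `model, year, nbp, cveg, gpp, npp`),
#'   optional `cells`, and `truth` (per-model `s_true`, `nbp_mean`,
#'   `cveg0`).
#' @export
sim_cmip_ensemble <- function(years = 2000:2019, n_models = 17,
                              s_true = NULL, nbp_mean = NULL, cveg0 = NULL,
                              gpp0 = 120, gpp_growth = 0.005, cue0 = 0.5,
                              noise_sd = 0.3, n_cells = 0, seed = 1) {
  if (n_models < 1) abort("`n_models` must be >= 1.")
  n <- length(years)
  set.seed(child_seed(seed, "ensemble"))
  s_true <- rep_len(s_true %||% pmax(rnorm(n_models, 1.6, 0.6), 1), n_models)
  nbp_mean <- rep_len(nbp_mean %||% rnorm(n_models, 1.2, 0.6), n_models)
  cveg0 <- rep_len(cveg0 %||% rnorm(n_models, 478, 86), n_models)
  gpp <- gpp0 * (1 + gpp_growth)^(seq_len(n) - 1)
  members <- purrr::map(seq_len(n_models), function(m) {
    shape <- seq(0.8, 1.2, length.out = n)  # gentle ramp in the sink
    nbp_clean <- nbp_mean[m] * shape / mean(shape)
    cveg <- cveg0[m] + cumsum(nbp_clean / s_true[m])
    tibble::tibble(
      model = sprintf("model_%02d", m),
      year = as.integer(years),
      nbp = nbp_clean + rnorm(n, 0, noise_sd),
      cveg = cveg,
      gpp = gpp,
      npp = cue0 * gpp
    )
  }) |> purrr::list_rbind()
  cells <- NULL
  if (n_cells > 0) {
    cells <- purrr::map(seq_len(n_models), function(m) {
      dv <- abs(rnorm(n_cells, 1, 0.5))
      tibble::tibble(
        model = sprintf("model_%02d", m),
        cell = seq_len(n_cells),
        delta_cveg = dv,
        cum_nbp = s_true[m] * dv + rnorm(n_cells, 0, noise_sd)
      )
    }) |> purrr::list_rbind()
  }
  list(
    members = members, cells = cells,
    truth = tibble::tibble(model = sprintf("model_%02d", seq_len(n_models)),
                           s_true = s_true, nbp_mean = nbp_mean,
                           cveg0 = cveg0)
  )
}

# cell-centered regular lat-lon axes with cosine-latitude areas (ha)
latlon_grid <- function(nlat, nlon, radius_m = 6371000) {
  dlat <- 180 / nlat
  dlon_rad <- 2 * pi / nlon
  lat_edges <- seq(-90, 90, length.out = nlat + 1)
  lat <- (lat_edges[-1] + lat_edges[-(nlat + 1)]) / 2
  lon <- seq(-180 + 180 / nlon, 180 - 180 / nlon, length.out = nlon)
  band_area_m2 <- radius_m^2 * dlon_rad *
    (sin(lat_edges[-1] * pi / 180) - sin(lat_edges[-(nlat + 1)] * pi / 180))
  tidyr::expand_grid(lat = lat, lon = lon) |>
    dplyr::mutate(area_ha = rep(band_area_m2, each = nlon) / 1e4)
}

#' Simulate a two-epoch vegetation biomass grid pair
#'
#' Builds a regular cell-centered lat-lon grid with cosine-latitude cell
#' areas and a positive early-epoch biomass field, then adds carbon to a
#' sparse subset of cells so that the area-weighted global change equals
#' `delta_cveg_true` exactly (accumulation confined to a few regions, as
#' satellite products show). Per-cell 1-sigma fields scale with the stock.
#'
#' @param nlat,nlon Grid shape (positive).
#' @param delta_cveg_true True global vegetation carbon change, Pg C.
#' @param sparse_fraction Fraction of cells carrying exactly zero change.
#' @param mean_density Mean early-epoch stock density, Mg C/ha.
#' @param epochs Length-2 labels (years) for the two epochs.
#' @param seed Integer seed.
#' @return List with `early` and `late` grids (tibbles
#'   `lat, lon, cveg, sigma, area_ha`, Mg C/ha with an `epoch` attribute)
#'   and `truth` (`delta_cveg`).
#' @export
sim_biomass_grids <- function(nlat = 36, nlon = 72, delta_cveg_true = 10.1,
                              sparse_fraction = 0.9, mean_density = 60,
                              epochs = c(2000, 2019), seed = 1) {
  if (nlat < 1 || nlon < 1) abort("Grid shape must be positive.")
  if (sparse_fraction < 0 || sparse_fraction >= 1) {
    abort("`sparse_fraction` must lie in [0, 1).")
  }
  grid <- latlon_grid(nlat, nlon)
  ncell <- nrow(grid)
  set.seed(child_seed(seed, "biomass"))
  early <- grid
  # positive, right-skewed stock field
  early$cveg <- mean_density * exp(rnorm(ncell, -0.125, 0.5))
  early$sigma <- 0.2 * early$cveg + 2
  n_active <- max(1L, floor((1 - sparse_fraction) * ncell))
  active <- sample.int(ncell, n_active)
  raw <- numeric(ncell)
  raw[active] <- abs(rnorm(n_active, 1, 0.5))
  total_raw_pgc <- sum(raw * grid$area_ha) * 1e-9
  change <- raw * (delta_cveg_true / total_raw_pgc)
  late <- early
  late$cveg <- early$cveg + change
  if (any(late$cveg < 0)) abort("Negative stock densities generated.")
  attr(early, "epoch") <- epochs[1]
  attr(late, "epoch") <- epochs[2]
  list(early = early, late = late,
       truth = list(delta_cveg = delta_cveg_true,
                    active_cells = sort(active)))
}
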