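test_that("simulated budgets close exactly and are deterministic", {
  b1 <- sim_budget_series(seed = 7)
  b2 <- sim_budget_series(seed = 7)
  b3 <- sim_budget_series(seed = 8)
  expect_identical(b1, b2)
  expect_false(identical(b1$ocean, b3$ocean))
  expect_equal(b1$fossil - b1$growth - b1$ocean - b1$land - b1$imbalance,
               rep(0, nrow(b1)))
  expect_true(all(c("fossil_sigma", "land_sigma") %in% names(b1)))
})

test_that("noise-free flat configuration yields constant series", {
  b <- sim_budget_series(years = 2000:2009, ff_start = 8, ff_growth = 0,
                         land_sink_true = 1,
                         noise_sd = c(growth = 0, ocean = 0), seed = 1)
  expect_equal(b$fossil, rep(8, 10))
  expect_equal(b$ocean, rep(0.29 * 8, 10))
  expect_equal(b$land, rep(1, 10))
})

test_that("budget generation rejects degenerate year ranges", {
  expect_error(sim_budget_series(years = 2000), "at least two")
})

test_that("hemispheric split conserves the global term and checks fractions", {
  b <- tibble(year = 2000:2001, fossil = c(8, 8.6), ocean = c(2.3, 2.5),
              fossil_sigma = 0.4, ocean_sigma = 0.4)
  h <- split_hemispheres(b, ff_north_fraction = 0.94,
                         ocean_north_fraction = 0.45)
  expect_equal(h$fossil_n + h$fossil_s, b$fossil)
  expect_equal(h$ocean_n + h$ocean_s, b$ocean)
  expect_equal(h$fossil_n[1], 7.52)
  expect_equal(h$fossil_s[1], 0.48)
  h1 <- split_hemispheres(b, ff_north_fraction = 1)
  expect_equal(h1$fossil_s, c(0, 0))
  h5 <- split_hemispheres(b, ff_north_fraction = 0.5)
  expect_equal(h5$fossil_n, h5$fossil_s)
  expect_error(split_hemispheres(b, ff_north_fraction = 1.2), "\\[0, 1\\]")
})

test_that("station generator is the forward model plus seeded noise", {
  w <- make_world(obs_noise_sd = 0)
  expect_equal(w$stations, w$clean)
  wn1 <- make_world(obs_noise_sd = 0.2, seed = 11)
  wn2 <- make_world(obs_noise_sd = 0.2, seed = 11)
  expect_identical(wn1$stations, wn2$stations)
  # doubling NH fossil emissions widens the mean interhemispheric gradient
  hemi2 <- w$hemi
  hemi2$fossil_n <- 2 * hemi2$fossil_n
  rec2 <- sim_station_records(hemi2, w$truth, obs_noise_sd = 0)
  grad1 <- mean(w$clean$co2_n - w$clean$co2_s)
  grad2 <- mean(rec2$stations$co2_n - rec2$stations$co2_s)
  expect_gt(grad2, grad1)
  # zero fluxes give flat records
  z <- w$hemi |> mutate(across(-year, ~0))
  lz <- w$truth |> mutate(land_n = 0, land_s = 0)
  flat <- sim_station_records(z, lz, init = c(north = 350, south = 350))
  expect_equal(unique(flat$stations$co2_n), 350)
  expect_equal(unique(flat$stations$co2_s), 350)
})

test_that("O2 record generator matches the single-term and round-trip budgets", {
  st <- o2_stoichiometry(alpha_f = 1.4, alpha_b = 1.1, z_ocean = 0)
  # fossil-only decline: rate equals -alpha_f * fossil in carbon units
  r <- sim_o2_records(2000:2009, fossil = 8, land_sink_true = 0, stoich = st)
  expect_equal(r$truth$rate_per_meg,
               rep(forward_o2_budget(8, 0, st)$do2_per_meg, 10))
  # linear round trip through OLS trend + partitioning
  rr <- sim_o2_records(2000:2019, fossil = 8, land_sink_true = 1, stoich = st)
  slope <- annual_trend(rr$o2, "per_meg")$slope
  do2_pgc <- per_meg_conversion(slope, st)$pgc_equiv
  p <- partition_sinks(dco2 = 8 - 1 - 2, do2 = do2_pgc, fossil = 8,
                       stoich = st)
  expect_equal(p$land, 1, tolerance = 1e-10)
  expect_equal(p$ocean, 2, tolerance = 1e-10)
  # determinism
  a <- sim_o2_records(2000:2009, 8, 1, noise_sd = 0.5, seed = 5)
  b <- sim_o2_records(2000:2009, 8, 1, noise_sd = 0.5, seed = 5)
  expect_identical(a$o2, b$o2)
})

test_that("ensemble generator embeds the true scale factor and CUE", {
  ens <- sim_cmip_ensemble(n_models = 3, s_true = c(1.0, 1.6, 2.2),
                           noise_sd = 0, cue0 = 0.5, seed = 2)
  sf <- compute_scale_factor(ens$members, window = c(2000, 2019))
  expect_equal(sort(tidy(sf)$s), c(1.0, 1.6, 2.2))
  expect_equal(sf$mean, 1.6)
  expect_equal(sf$sd, 0.6)
  cue <- carbon_use_efficiency(ens$members)
  expect_equal(unique(cue$cue), 0.5)
  expect_identical(
    sim_cmip_ensemble(seed = 4)$members,
    sim_cmip_ensemble(seed = 4)$members
  )
})

test_that("biomass grids conserve the true global change and are sparse", {
  g <- sim_biomass_grids(nlat = 18, nlon = 36, delta_cveg_true = 10.1,
                         sparse_fraction = 0.9, seed = 3)
  change <- g$late
  change$cveg <- g$late$cveg - g$early$cveg
  expect_equal(grid_total_pgc(change), 10.1, tolerance = 1e-12)
  expect_gte(mean(change$cveg == 0), 0.9)
  expect_true(all(g$early$cveg >= 0) && all(g$late$cveg >= 0))
  expect_identical(sim_biomass_grids(seed = 9)$late,
                   sim_biomass_grids(seed = 9)$late)
  # cosine-latitude areas: equatorial cells are the largest; total is Earth
  areas <- g$early |> dplyr::summarise(a = sum(area_ha))
  expect_equal(areas$a * 1e4 / 1e12, 510, tolerance = 0.01)  # ~5.1e14 m2
  expect_gt(g$early$area_ha[which(abs(g$early$lat) < 6)][1],
            g$early$area_ha[which(abs(g$early$lat) > 80)][1])
})
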