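test_that("forward model reaches the closed-form steady gradient", {
  h <- tibble(year = 1:400, fossil_n = 4, fossil_s = 0,
              ocean_n = 0, ocean_s = 0)
  l <- tibble(year = 1:400, land_n = 0, land_s = 0)
  p <- transport_params(tau = 1.3, kappa_global = 2.124)
  st <- forward_two_box(h, l, init = c(north = 300, south = 300), params = p)
  # steady state of the gradient recursion: E * tau / (2 * kappa_h)
  expect_equal(tail(st$co2_n - st$co2_s, 1), 4 * 1.3 / (2 * 1.062),
               tolerance = 1e-6)
})

test_that("forward model is flat with zero fluxes and symmetric with equal sources", {
  h0 <- tibble(year = 1:20, fossil_n = 0, fossil_s = 0,
               ocean_n = 0, ocean_s = 0)
  l0 <- tibble(year = 1:20, land_n = 0, land_s = 0)
  st0 <- forward_two_box(h0, l0, init = c(north = 340, south = 340))
  expect_equal(unique(st0$co2_n), 340)
  expect_equal(unique(st0$co2_s), 340)
  heq <- h0 |> mutate(fossil_n = 3, fossil_s = 3)
  steq <- forward_two_box(heq, l0, init = c(north = 340, south = 340))
  expect_equal(steq$co2_n - steq$co2_s, rep(0, 21))
})

test_that("forward runs conserve atmospheric carbon mass exactly", {
  w <- make_world(seed = 5)
  p <- transport_params()
  st <- w$clean
  mass_change <- p$kappa_hemisphere *
    ((tail(st$co2_n, 1) - st$co2_n[1]) + (tail(st$co2_s, 1) - st$co2_s[1]))
  net_flux <- sum(w$hemi$fossil_n + w$hemi$fossil_s -
                    w$hemi$ocean_n - w$hemi$ocean_s -
                    w$truth$land_n - w$truth$land_s)
  expect_equal(mass_change, net_flux, tolerance = 1e-10)
})

test_that("inversion inverts the forward model exactly", {
  w <- make_world(seed = 13)
  inv <- invert_two_box(w$stations, w$hemi)
  expect_lt(max(abs(tidy(inv)$land_n - w$truth$land_n)), 1e-9)
  expect_lt(max(abs(tidy(inv)$land_s - w$truth$land_s)), 1e-9)
  # cumulative sums agree too
  expect_equal(sum(tidy(inv)$land_n), sum(w$truth$land_n), tolerance = 1e-9)
})

test_that("flat equal concentrations with zero fluxes invert to zero sinks", {
  h <- tibble(year = 2000:2004, fossil_n = 0, fossil_s = 0,
              ocean_n = 0, ocean_s = 0)
  st <- tibble(year = 2000:2005, co2_n = 360, co2_s = 360)
  inv <- invert_two_box(st, h)
  expect_equal(tidy(inv)$land_n, rep(0, 5))
  expect_equal(tidy(inv)$land_s, rep(0, 5))
})

test_that("constrained mode satisfies the global-residual identity exactly", {
  w <- make_world(seed = 21)
  gl <- global_land_of(w$budget)
  inv <- invert_two_box(w$stations, w$hemi, global_land = gl)
  expect_equal(tidy(inv)$land_n + tidy(inv)$land_s, gl$value)
  expect_identical(inv$mode, "constrained")
})

test_that("raising NH fossil emissions lowers the inferred northern sink", {
  w <- make_world(seed = 3)
  base <- tidy(invert_two_box(w$stations, w$hemi))$land_n
  hemi_hi <- w$hemi
  hemi_hi$fossil_n <- hemi_hi$fossil_n * 1.1
  # at fixed observations, explaining larger emissions with the same CO2
  # record requires a stronger inferred northern sink, year by year
  hi <- tidy(invert_two_box(w$stations, hemi_hi))$land_n
  expect_true(all(hi > base))
  # and in the forward direction the steady gradient widens
  h <- tibble(year = 1:200, fossil_n = 4, fossil_s = 0,
              ocean_n = 0, ocean_s = 0)
  l <- tibble(year = 1:200, land_n = 0, land_s = 0)
  g1 <- with(tail(forward_two_box(h, l), 1), co2_n - co2_s)
  h$fossil_n <- 5
  g2 <- with(tail(forward_two_box(h, l), 1), co2_n - co2_s)
  expect_gt(g2, g1)
})

test_that("the -6% fossil / +8% ocean scenario strictly lowers the NH sink", {
  w <- make_world(seed = 17)
  base <- tidy(invert_two_box(w$stations, w$hemi))$land_n
  hemi_adj <- apply_scenario(w$hemi, ff_scale = 0.94, ocean_scale = 1.08)
  adj <- tidy(invert_two_box(w$stations, hemi_adj))$land_n
  expect_true(all(adj < base))
})

test_that("apply_scenario scales fossil and ocean terms with uncertainties", {
  h <- tibble(year = 2000, fossil_n = 8.6, fossil_s = 0.5,
              ocean_n = 1, ocean_s = 1.3,
              fossil_n_sigma = 0.4, ocean_n_sigma = 0.2)
  expect_identical(apply_scenario(h, 1, 1), h)
  s <- apply_scenario(h, ff_scale = 0.94, ocean_scale = 1.08)
  expect_equal(s$fossil_n, 8.084)
  expect_equal(s$fossil_n_sigma, 0.376)
  expect_equal(s$ocean_s, 1.404)
  b <- gcp_budget_2000_2019()
  sb <- apply_scenario(b, ff_scale = 0.94, ocean_scale = 1.08)
  expect_equal(sb$mean[sb$term == "fossil"], 8.084)
  expect_equal(sb$mean[sb$term == "ocean"], 2.7)
  expect_error(apply_scenario(h, ff_scale = 0), "> 0")
})

test_that("Monte-Carlo inversion is seeded and covers the truth", {
  w <- make_world(seed = 29, obs_noise_sd = 0.1)
  gl <- global_land_of(w$budget)
  inv1 <- invert_two_box(w$stations, w$hemi, global_land = gl,
                         obs_sigma = 0.1, mc = list(n = 300, seed = 8))
  inv2 <- invert_two_box(w$stations, w$hemi, global_land = gl,
                         obs_sigma = 0.1, mc = list(n = 300, seed = 8))
  expect_identical(tidy(inv1), tidy(inv2))
  expect_true(all(tidy(inv1)$land_n_sigma > 0))
})

test_that("aggregate_series integrates, averages by decade, and by period", {
  s <- tibble(year = 1959:2022, value = 1)
  expect_equal(tail(aggregate_series(s, mode = "cumulative")$cumulative, 1),
               64)
  s3 <- tibble(year = 2001:2003, value = c(1, 2, 3))
  expect_equal(aggregate_series(s3, mode = "period_mean"), 2)
  d <- aggregate_series(tibble(year = 1995:2004, value = rep(c(1, 3), each = 5)),
                        mode = "decadal_mean")
  expect_equal(d$mean, c(1, 3))
  expect_equal(d$decade, c(1990, 2000))
  expect_error(aggregate_series(s3, mode = "period_mean",
                                window = c(2010, 2012)), "no years")
})
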