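test_that("carbon use efficiency is NPP/GPP per model-year", {
  m <- tibble(model = "a", year = 2000:2002, gpp = c(60, 60, 80),
              npp = c(30, 60, 40))
  cue <- carbon_use_efficiency(m)
  expect_equal(cue$cue, c(0.5, 1.0, 0.5))
  flat <- tibble(model = "b", year = 2000:2004, gpp = 100, npp = 45)
  expect_equal(unique(carbon_use_efficiency(flat)$cue), 0.45)
  bad <- tibble(model = "c", year = 2000, gpp = 0, npp = 0)
  expect_error(carbon_use_efficiency(bad), "GPP")
})

test_that("NPP down-regulation follows the damped relative-increment recursion", {
  gpp <- 100 * 1.01^(0:70)
  npp <- downregulate_npp(gpp, npp_initial = 50, damping = 0.5)
  # closed form: each year NPP grows by half of GPP's 1% growth
  expect_equal(npp[71] / npp[1], 1.005^70, tolerance = 1e-12)
  expect_equal(npp[71] / npp[1], 1.418, tolerance = 1e-3)
  expect_equal(gpp[71] / gpp[1], 2.007, tolerance = 1e-3)
  # end CUE is the start CUE shrunk by (1.005/1.01)^70
  expect_equal((npp[71] / gpp[71]) / (npp[1] / gpp[1]),
               (1.005 / 1.01)^70, tolerance = 1e-12)
  # limits: damping 1 tracks GPP (constant CUE); damping 0 freezes NPP
  track <- downregulate_npp(gpp, 50, damping = 1)
  expect_equal(track / gpp, rep(0.5, 71), tolerance = 1e-12)
  expect_equal(downregulate_npp(gpp, 50, damping = 0), rep(50, 71))
  expect_error(downregulate_npp(gpp, 50, damping = 2), "\\[0, 1\\]")
  expect_error(downregulate_npp(c(-1, 1), 50), "GPP")
})

test_that("damped NPP is ordered in damping and has non-increasing CUE", {
  set.seed(31)
  for (i in 1:5) {
    gpp <- cumsum(abs(rnorm(40, 1, 0.2))) + 80  # non-decreasing GPP
    a <- downregulate_npp(gpp, 40, damping = 0.3)
    b <- downregulate_npp(gpp, 40, damping = 0.8)
    expect_true(all(a <= b + 1e-12))
    cue <- a / gpp
    expect_true(all(diff(cue) <= 1e-12))
  }
})

test_that("ensemble bias statistics reproduce the published comparisons", {
  # vegetation carbon accumulation: models vs satellite estimate
  vals <- c(10, 15.7, 21.4)  # mean 15.7
  s <- ensemble_bias_stats(vals, reference = 10.1)
  expect_equal(glance(s)$bias_pct, 100 * (15.7 - 10.1) / 10.1)
  expect_equal(round(glance(s)$bias_pct), 55)
  # standing stock: slight positive bias of ~16%
  s2 <- ensemble_bias_stats(c(400, 478, 556), reference = 411)
  expect_equal(round(glance(s2)$bias_pct), 16)
  expect_equal(glance(ensemble_bias_stats(c(1, 3), 2))$bias_pct, 0)
  # sd uses the n-1 denominator and is order-invariant
  expect_equal(s$sd, sd(vals))
  expect_equal(glance(ensemble_bias_stats(rev(vals), 10.1)),
               glance(s))
  expect_error(ensemble_bias_stats(1, 2), "two models")
})

test_that("variance explained equals a direct correlation oracle", {
  d <- tibble(delta_cveg = c(1, 2, 3, 4), cum_nbp = c(1.2, 1.9, 3.1, 3.8))
  v <- variance_explained(d, n_perm = 200, seed = 1)
  expect_equal(v$r_squared, 0.9878, tolerance = 1e-4)
  expect_equal(v$r_squared, cor(d$delta_cveg, d$cum_nbp)^2)
  # brute-force oracle on random inputs up to length 100
  set.seed(77)
  for (n in c(5, 20, 100)) {
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    vv <- variance_explained(tibble(delta_cveg = x, cum_nbp = y),
                             n_perm = 50, seed = 2)
    num <- sum((x - mean(x)) * (y - mean(y)))^2
    den <- sum((x - mean(x))^2) * sum((y - mean(y))^2)
    expect_equal(vv$r_squared, num / den, tolerance = 1e-12)
  }
  # exact proportionality gives R^2 = 1
  expect_equal(variance_explained(tibble(delta_cveg = 1:5,
                                         cum_nbp = 2 * (1:5)),
                                  n_perm = 50)$r_squared, 1)
  expect_error(variance_explained(tibble(delta_cveg = c(1, 1, 1),
                                         cum_nbp = 1:3), n_perm = 10),
               "Zero variance")
})

test_that("permutation p-values are seeded and detect strong association", {
  set.seed(5)
  d <- tibble(delta_cveg = rnorm(17), cum_nbp = NA)
  d$cum_nbp <- 1.6 * d$delta_cveg + rnorm(17, 0, 0.3)
  v1 <- variance_explained(d, n_perm = 1000, seed = 9)
  v2 <- variance_explained(d, n_perm = 1000, seed = 9)
  expect_identical(v1, v2)
  expect_lt(v1$p_value, 0.01)
})

test_that("within-model spatial mode averages per-member R^2", {
  ens <- sim_cmip_ensemble(n_models = 4, noise_sd = 0, n_cells = 30,
                           seed = 12)
  v <- variance_explained(ens$cells, mode = "within_model_spatial")
  # noise-free cells are exactly proportional per member
  expect_equal(v$r_squared_mean, 1, tolerance = 1e-12)
  expect_equal(v$n_models, 4)
  noisy <- sim_cmip_ensemble(n_models = 4, noise_sd = 0.3, n_cells = 50,
                             seed = 12)
  vn <- variance_explained(noisy$cells, mode = "within_model_spatial")
  expect_lt(vn$r_squared_mean, 1)
  expect_gt(vn$r_squared_mean, 0.3)
  per <- attr(vn, "per_model")
  expect_equal(nrow(per), 4)
})

test_that("cross-model spread in S drives the cveg-NBP association", {
  # members built with exact proportionality cum NBP = s * dCVeg:
  # the cross-model R^2 must match the direct correlation of those scalars
  ens <- sim_cmip_ensemble(n_models = 8, noise_sd = 0, seed = 3)
  sf <- compute_scale_factor(ens$members, c(2000, 2019))
  d <- tidy(sf) |>
    dplyr::transmute(delta_cveg = delta_cveg, cum_nbp = cum_nbp)
  v <- variance_explained(d, n_perm = 100, seed = 1)
  expect_equal(v$r_squared, cor(d$delta_cveg, d$cum_nbp)^2)
})
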