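# shared fixtures, built in code

library(dplyr)
library(tibble)

# a small calibrated synthetic world: closed budget, hemispheric split,
# true hemispheric land sinks (80% north), forward-model station records
make_world <- function(years = 2000:2019, seed = 42, obs_noise_sd = 0,
                       north_share = 0.8, ...) {
  budget <- sim_budget_series(years = years, seed = seed, ...)
  hemi <- split_hemispheres(budget)
  truth <- tibble::tibble(
    year = budget$year,
    land_n = north_share * attr(budget, "truth")$land_sink_true,
    land_s = (1 - north_share) * attr(budget, "truth")$land_sink_true
  )
  rec <- sim_station_records(hemi, truth, obs_noise_sd = obs_noise_sd,
                             seed = seed)
  list(budget = budget, hemi = hemi, truth = truth,
       stations = rec$stations, clean = rec$clean)
}

global_land_of <- function(budget) {
  tibble::tibble(year = budget$year, value = budget$land,
                 sigma = budget$land_sigma)
}
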