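test_that("CO2-to-dry matter conversion is the stoichiometric product", {
  expect_equal(co2_to_dry_matter(0), 0)
  expect_equal(co2_to_dry_matter(44, 30 / 44), 30)
  expect_equal(co2_to_dry_matter(10, 0.6818), 6.818)
  expect_equal(co2_to_dry_matter(-10, 0.5), -5) # sign-preserving
  expect_error(co2_to_dry_matter(1, 0), "0, 1")
})

test_that("season simulation assembles the daily balance exactly", {
  weather <- toy_weather(30)
  canopy <- interpolate_canopy(toy_canopy_obs(), das_range = c(0, 29))
  params <- carbon_params()
  sim <- simulate_season(weather, canopy, params)

  # per-day assembly against the sub-module functions, hand-composed
  for (i in c(1, 15, 30)) {
    p_ref <- daily_photosynthesis(weather$tmin[i], weather$tmax[i],
                                  weather$radiation[i], weather$day_length[i],
                                  canopy$light_interception[canopy$das == sim$das[i]],
                                  params$photo)
    r_ref <- daily_respiration(weather$tmin[i], weather$tmax[i],
                               weather$day_length[i],
                               canopy$shoot_surface[canopy$das == sim$das[i]],
                               canopy$cluster_weight[canopy$das == sim$das[i]],
                               canopy$clusters[canopy$das == sim$das[i]],
                               canopy$leaf_area_increment[canopy$das == sim$das[i]],
                               params$resp)
    expect_equal(sim$p_gross_vine[i], p_ref)
    expect_equal(sim$r_total_vine[i], r_ref)
    expect_equal(sim$co2_balance[i], p_ref - r_ref)
  }
  # conservation: cumulative DM is exactly the converted running balance
  expect_equal(sim$dm_cumulative,
               cumsum(sim$co2_balance) * params$co2_to_dm)
  expect_equal(sim$dm_daily, sim$co2_balance * params$co2_to_dm)
})

test_that("dark seasons lose dry matter monotonically; more light never hurts", {
  weather <- toy_weather(20)
  canopy <- interpolate_canopy(toy_canopy_obs(), das_range = c(0, 19))
  dark <- weather
  dark$radiation <- 0
  sim_dark <- simulate_season(dark, canopy)
  expect_true(all(diff(sim_dark$dm_cumulative) < 0))

  sim <- simulate_season(weather, canopy)
  brighter <- weather
  brighter$radiation <- weather$radiation * 1.3
  sim_b <- simulate_season(brighter, canopy)
  expect_gte(tail(sim_b$dm_cumulative, 1), tail(sim$dm_cumulative, 1))
})

test_that("season simulation is deterministic and reports missing days", {
  weather <- toy_weather(25)
  canopy <- interpolate_canopy(toy_canopy_obs(), das_range = c(0, 24))
  s1 <- simulate_season(weather, canopy)
  s2 <- simulate_season(weather, canopy)
  expect_identical(s1, s2)
  short <- canopy[canopy$das <= 20, ]
  expect_error(simulate_season(weather, short), "DAS 21")
})

test_that("calibration recovers a known multiplier on the saturated rate", {
  cfg <- synthetic_config(seed = 11)
  weather <- generate_weather(cfg)
  canopy <- interpolate_canopy(generate_canopy(cfg),
                               das_range = c(0, cfg$season_length - 1))
  params <- carbon_params()
  obs_das <- round(seq(30, cfg$season_length - 1, length.out = 8))

  # factor 1: self-consistency
  sim <- simulate_season(weather, canopy, params)
  obs <- tibble::tibble(das = obs_das,
                        dm = sim$dm_cumulative[match(obs_das, sim$das)])
  cal <- calibrate_scale(weather, canopy, params, obs)
  expect_equal(cal$factor, 1, tolerance = 0.01)

  # factor 1.5, noise-free
  p15 <- params
  p15$photo$pn_max <- params$photo$pn_max * 1.5
  sim15 <- simulate_season(weather, canopy, p15)
  obs15 <- tibble::tibble(das = obs_das,
                          dm = sim15$dm_cumulative[match(obs_das, sim15$das)])
  cal15 <- calibrate_scale(weather, canopy, params, obs15)
  expect_equal(cal15$factor, 1.5, tolerance = 0.01)
  expect_equal(cal15$params$photo$pn_max, 1.5e-3, tolerance = 0.01)

  # 5% multiplicative noise, fixed seed: within 10%
  withr::with_seed(99, {
    noisy <- obs15
    noisy$dm <- noisy$dm * (1 + rnorm(nrow(noisy), 0, 0.05))
    cal_n <- calibrate_scale(weather, canopy, params, noisy)
    expect_equal(cal_n$factor, 1.5, tolerance = 0.10)
  })

  expect_error(calibrate_scale(weather, canopy, params, obs[1:2, ]),
               "At least 3")
})
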