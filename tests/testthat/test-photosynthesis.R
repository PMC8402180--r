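test_that("leaf light response saturates as a rectangular hyperbola", {
  expect_equal(leaf_light_response(0, 2, 1e-3), 0)
  # half-saturation where alpha' I = Pmax
  i_half <- 1e-3 / (3.9e-6)
  expect_equal(leaf_light_response(i_half, 3.9, 1e-3), 5e-4)
  expect_equal(leaf_light_response(1e6, 2, 1e-3), 1e-3, tolerance = 0.01)
  expect_true(all(leaf_light_response(c(10, 100, 1000), 2, 1e-3) < 1e-3))
})

test_that("analytic canopy integral matches the layered Beer-Lambert oracle", {
  params <- photosynthesis_params(pn_max = 1e-3, quantum_yield = 2.0, k = 0.55)
  lai <- -log(1 - 0.16) / 0.55
  ref <- oracle_canopy_layers(500, 2.0, 1e-3, 0.55, lai)
  expect_equal(canopy_instantaneous(500, params, 0.16), ref,
               tolerance = 0.005)
  # grid across irradiance, yield, saturation rate, extinction, interception
  grid <- expand.grid(i = c(50, 300, 900), alpha = c(0.67, 3.9),
                      pmax = c(5e-4, 1e-3), k = c(0.5, 0.6),
                      li = c(0.05, 0.16, 0.18))
  for (r in seq_len(nrow(grid))) {
    p <- photosynthesis_params(pn_max = grid$pmax[r],
                               quantum_yield = grid$alpha[r], k = grid$k[r])
    lai <- -log(1 - grid$li[r]) / grid$k[r]
    ref <- oracle_canopy_layers(grid$i[r], grid$alpha[r], grid$pmax[r],
                                grid$k[r], lai)
    expect_equal(canopy_instantaneous(grid$i[r], p, grid$li[r]), ref,
                 tolerance = 0.005)
  }
})

test_that("canopy photosynthesis vanishes without light or canopy and is bounded", {
  params <- photosynthesis_params()
  expect_equal(canopy_instantaneous(0, params, 0.16), 0)
  expect_equal(canopy_instantaneous(500, params, 0), 0)
  expect_error(canopy_instantaneous(500, params, 1), "infinite")
  # big-leaf bound Pmax * L, approached as I -> infinity
  lai <- -log(1 - 0.16) / params$k
  big <- canopy_instantaneous(1e8, params, 0.16)
  expect_lt(big, params$pn_max * lai * (1 + 1e-9))
  expect_equal(big, params$pn_max * lai, tolerance = 0.01)
})

test_that("temperature factor is the anchored piecewise quadratic", {
  params <- photosynthesis_params()
  expect_equal(temperature_factor(27.5, params), 1)
  expect_equal(temperature_factor(10, params), 0)
  expect_equal(temperature_factor(45, params), 0)
  expect_equal(temperature_factor(18.75, params), 0.75) # hand value
  expect_equal(temperature_factor(c(-5, 60), params), c(0, 0))
  # continuity across the optimum
  expect_equal(temperature_factor(27.5 - 1e-8, params),
               temperature_factor(27.5 + 1e-8, params), tolerance = 1e-6)
})

test_that("daily photosynthesis matches a fine-time-step reference", {
  params <- photosynthesis_params(pn_max = 1e-3, quantum_yield = 2.0,
                                  k = 0.55, ground_area = 3.6)
  got <- daily_photosynthesis(tmin = 18, tmax = 32, radiation = 25,
                              day_length = 54000, light_interception = 0.16,
                              params = params)
  ref <- oracle_daily_photo(18, 32, 25, 54000, 0.16, params)
  expect_equal(got, ref, tolerance = 0.005)
  expect_equal(daily_photosynthesis(18, 32, 0, 54000, 0.16, params), 0)
  expect_equal(daily_photosynthesis(18, 32, 25, 54000, 0, params), 0)
})

test_that("daily photosynthesis is monotone in its drivers and step-converged", {
  base <- list(tmin = 15, tmax = 27, radiation = 20, day_length = 50000,
               li = 0.12)
  val <- function(rad = base$radiation, li = base$li, alpha = 2,
                  pmax = 1e-3, n_steps = 48L) {
    p <- photosynthesis_params(pn_max = pmax, quantum_yield = alpha)
    daily_photosynthesis(base$tmin, base$tmax, rad, base$day_length, li, p,
                         n_steps = n_steps)
  }
  v0 <- val()
  expect_gt(val(rad = 25), v0)
  expect_gt(val(li = 0.16), v0)
  expect_gt(val(alpha = 3), v0)
  expect_gt(val(pmax = 1.5e-3), v0)
  # halving the step changes the integral by < 0.2%
  expect_equal(val(n_steps = 96L), v0, tolerance = 0.002)
})
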