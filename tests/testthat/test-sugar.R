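make_sim_stub <- function(das, dm) {
  out <- tibble::tibble(das = das, date = as.Date("2014-04-01") + das,
                        p_gross_vine = NA_real_, r_total_vine = NA_real_,
                        co2_balance = NA_real_, dm_daily = NA_real_,
                        dm_cumulative = dm)
  class(out) <- c("vine_sim", class(out))
  out
}

test_that("sugar regression recovers exact and noisy linear relations", {
  sim <- make_sim_stub(1:3, c(10, 20, 30))
  fit <- fit_brix_dm(tibble::tibble(das = 1:3, brix = c(12, 14, 16)), sim)
  expect_equal(fit$slope, 0.2)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$r2, 1)

  flat <- fit_brix_dm(tibble::tibble(das = 1:3, brix = rep(15, 3)), sim)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  # noisy points against the closed-form normal equations
  withr::with_seed(7, {
    dm <- seq(200, 1100, length.out = 10)
    brix <- 15 + 0.005 * dm + rnorm(10, 0, 0.5)
    sim10 <- make_sim_stub(1:10, dm)
    fit10 <- fit_brix_dm(tibble::tibble(das = 1:10, brix = brix), sim10)
    ref <- oracle_ols(dm, brix)
    expect_equal(fit10$slope, unname(ref["slope"]))
    expect_equal(fit10$intercept, unname(ref["intercept"]))
  })
})

test_that("sugar regression rejects degenerate inputs", {
  sim <- make_sim_stub(1:3, c(10, 20, 30))
  expect_error(fit_brix_dm(tibble::tibble(das = 1:2, brix = c(12, 14)), sim),
               "At least 3")
  expect_error(fit_brix_dm(tibble::tibble(das = c(1, 2, 9), brix = c(12, 14, 15)),
                           sim), "outside")
  const <- make_sim_stub(1:3, rep(10, 3))
  expect_error(fit_brix_dm(tibble::tibble(das = 1:3, brix = c(12, 14, 16)),
                           const), "constant")
})

test_that("r2 is invariant under affine rescaling of dry matter", {
  withr::with_seed(3, {
    dm <- seq(100, 900, length.out = 8)
    brix <- 10 + 0.01 * dm + rnorm(8, 0, 0.3)
    f1 <- fit_brix_dm(tibble::tibble(das = 1:8, brix = brix),
                      make_sim_stub(1:8, dm))
    f2 <- fit_brix_dm(tibble::tibble(das = 1:8, brix = brix),
                      make_sim_stub(1:8, 3.7 * dm + 250))
    expect_equal(f1$r2, f2$r2)
  })
})

test_that("sugar prediction applies the fitted line with a zero floor", {
  sim <- make_sim_stub(1:3, c(10, 20, 30))
  fit <- fit_brix_dm(tibble::tibble(das = 1:3, brix = c(12, 14, 16)), sim)
  expect_equal(predict_brix(fit, 0), fit$intercept)
  expect_equal(predict_brix(fit, 50), 20)
  expect_equal(predict_brix(fit, -1e5), 0)
  # residual mean zero on the fitting data
  expect_equal(mean(predict_brix(fit, sim$dm_cumulative) -
                      c(12, 14, 16)), 0, tolerance = 1e-10)
})

test_that("predicted sugar is non-increasing in cluster count", {
  cfg <- synthetic_config(seed = 5)
  season <- generate_season(cfg)
  fit <- fit_brix_dm(season$brix_obs, season$sim)
  params <- carbon_params()
  sc <- run_cluster_scenarios(season$weather, season$canopy, params, fit,
                              c(0, 6, 10.4, 12))
  # baseline cluster count equals one scenario: identical trajectories
  base <- sc$brix[is.na(sc$clusters)]
  expect_equal(sc$brix[!is.na(sc$clusters) & sc$clusters == 10.4], base)
  wide <- tidyr::pivot_wider(dplyr::filter(sc, !is.na(clusters)),
                             id_cols = "das", names_from = "clusters",
                             values_from = "brix")
  expect_true(all(wide$`0` >= wide$`6`))
  expect_true(all(wide$`6` >= wide$`10.4`))
  expect_true(all(wide$`10.4` >= wide$`12`))
})

test_that("tidy and glance expose the regression in broom shape", {
  sim <- make_sim_stub(1:5, c(10, 20, 30, 40, 55))
  fit <- fit_brix_dm(tibble::tibble(das = 1:5,
                                    brix = c(12, 14.1, 15.9, 18, 20.5)), sim)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r2)
  expect_equal(gl$nobs, 5)
})
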