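# vitisim

Daily carbon-balance simulation and berry-sugar prediction for grapevine
canopies.

Viticulturists comparing training systems (e.g. vertical shoot positioning,
VSP, versus single high wire, SHW) need to know how canopy architecture
translates into seasonal dry-matter accumulation and, ultimately, berry
sugar at harvest. `vitisim` implements that chain as a tested R pipeline:

1. **Photosynthesis** — a rectangular-hyperbola leaf light response
   P(I) = α′·I·P<sub>max</sub> / (α′·I + P<sub>max</sub>) integrated
   analytically through a Beer–Lambert canopy,
   P<sub>c</sub> = (P<sub>max</sub>/K)·ln[(α′KI + P<sub>max</sub>) /
   (α′KI·e<sup>−KL</sup> + P<sub>max</sub>)],
   where the effective LAI L = −ln(1 − LI)/K comes from *measured* canopy
   light interception. Integrated over a half-sine daily irradiance profile
   and scaled by a temperature factor, it yields g CO₂ vine⁻¹ day⁻¹.
2. **Respiration** — shoot and cluster maintenance pools with an Arrhenius
   temperature response (default E<sub>a</sub> = 51,200 J mol⁻¹, i.e.
   Q₁₀ = 2 over 20–30 °C), day/night weighted by day-length fraction, plus
   growth respiration proportional to new leaf area.
3. **Carbon balance** — daily CO₂ balance × 30/44 g DM per g CO₂,
   accumulated from sprouting to harvest; optional one-parameter
   calibration of P<sub>max</sub> against measured dry matter.
4. **Sugar model** — OLS regression of °Brix on cumulative dry matter
   between veraison and harvest, and re-simulated sugar trajectories under
   altered cluster counts (crop-load scenarios).
5. **Evaluation** — R², MAE, RRMSE and PBIAS
   (= 100·Σ(Oᵢ−Pᵢ)/ΣOᵢ; under-prediction is positive).
6. **Synthetic seasons** — a seeded generator for weather, canopy
   trajectories and observations with the statistical structure of a
   temperate vineyard trial, so the whole pipeline runs and tests without
   field data.

Every user-facing function takes a data frame and returns a tibble; fitted
objects have `tidy()`/`glance()` methods and each result type has an
`autoplot()`.

## Worked example

```r
library(vitisim)

season <- generate_season(synthetic_config(seed = 42, profile = "shw"))
fit <- fit_brix_dm(season$brix_obs, season$sim)
fit
#> Sugar-dry matter regression (OLS)
#>   Brix = 1.6096 + 0.02003 x DM (g/vine)
#>   R^2 = 0.984 on n = 10 observations

pred <- season$sim$dm_cumulative[match(season$dm_obs$das, season$sim$das)]
evaluate_fit(season$dm_obs$dm, pred)
#> Model evaluation
#>   R^2 = 0.995  MAE = 23.16  RRMSE = 0.057  PBIAS = -1.93%  (n = 8)

tail(season$sim, 1)[, c("das", "dm_cumulative")]
#> # A tibble: 1 x 2
#>     das dm_cumulative
#>   <int>         <dbl>
#> 1   164         1189.
```

The fitted slope and intercept recover the generator's true sugar–dry
matter relation (0.019 °Brix g⁻¹, 2.8 °Brix) within sampling noise; the
evaluation block compares the simulated dry-matter curve against the noisy
synthetic observations (about −2 % bias here: the simulation ran slightly
high relative to the sampled observations).
The final row shows the season's accumulated dry matter per vine (~1.2 kg).
`run_pipeline(default_run_config(), out_dir = "results")` chains all stages
and writes the per-day table, fit, evaluation and scenario trajectories
with a configuration digest.

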