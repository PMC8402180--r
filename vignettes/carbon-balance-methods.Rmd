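---
title: "Methods: daily grapevine carbon balance and sugar prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily grapevine carbon balance and sugar prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitisim)
```

## The model

`vitisim` simulates the seasonal carbon economy of a single grapevine at a
daily time step. Two sub-modules produce daily fluxes in g CO~2~ per vine:

**Photosynthesis.** The leaf light response is a rectangular hyperbola,
$P(I) = \alpha' I P_{max} / (\alpha' I + P_{max})$, with quantum yield
$\alpha$ (µg CO~2~ J^-1^, converted internally to g J^-1^) as its initial
slope and $P_{max}$ (g CO~2~ m^-2^ s^-1^) its saturation. Light attenuates
through the canopy by Beer–Lambert with extinction coefficient $K$, so the
leaf-level response integrates in closed form over canopy depth:

$$P_c(I) = \frac{P_{max}}{K}\,
  \ln\frac{\alpha' K I + P_{max}}{\alpha' K I e^{-KL} + P_{max}},$$

per m^2^ of ground. The effective leaf-area index $L$ is not a free input:
measured canopy light interception $LI$ (a ceptometer quantity, honoured as
data) is inverted through $L = -\ln(1-LI)/K$, so the model consumes exactly
what a vineyard trial measures — $P_{max}$, $\alpha$, $K$, $LI$ and the
ground area allotted per vine. The daily total integrates $P_c$ over a
half-sine irradiance profile (below), scaled by a piecewise-quadratic
temperature factor on the daily mean (0 at 10 °C, 1 at 27.5 °C, 0 at 45 °C
by default; vines have no measured sub-daily temperatures, so the daily
mean is the only usable driver). These anchors are configurable; no field
calibration of them is implied.

**Respiration.** Organ maintenance respiration (shoot surface at
`r20_shoot` g CO~2~ m^-2^ day^-1^; clusters at `r20_cluster` g CO~2~ g^-1^
fresh weight day^-1^, both referenced to 20 °C) responds to temperature by
Arrhenius, $\exp[(E_a/R)(1/T_{ref} - 1/T)]$. The default activation energy
51,200 J mol^-1^ corresponds to Q~10~ = 2 over 20–30 °C. Day and night are
weighted by the day-length fraction of the 24 h cycle, at representative
temperatures $(T_{max}+T_{mean})/2$ and $(T_{min}+T_{mean})/2$: this is the
natural use of day length in a model whose inputs are daily extremes.
Growth respiration is proportional to the daily increment of main leaf area
(`growth_coeff` g CO~2~ m^-2^ of new leaf); the increment enters without a
temperature law because new-tissue construction cost per unit area is
approximately temperature-independent. The split of maintenance
(temperature-driven) versus growth (increment-driven) is the minimal
structure consistent with the organ inputs the model receives.

The daily CO~2~ balance $P - R$ is converted to dry matter with the CH~2~O
stoichiometric factor 30/44 ≈ 0.68 g DM per g CO~2~ (configurable) and
accumulated. Negative daily balances are kept: early-season respiration can
exceed photosynthesis, and clamping would silently destroy mass
conservation, which the tests check exactly.

Lateral (secondary) leaf area is carried through the data model but
excluded from photosynthesis. This mirrors the model structure used in
trellis-comparison work, and it is the known mechanism behind
underestimation of dry matter for training systems with large lateral
canopies late in the season — a limitation, not an oversight.

## Weather derivations

Day length is geometric: Cooper's declination
$\delta = 23.44^\circ \sin(2\pi(284+n)/365)$ with the sunset hour angle,
no refraction or twilight. Published vineyard input tables sometimes show
day-length maxima a few percent above the geometric value (the convention
used to produce them, e.g. twilight inclusion, is rarely stated), so
seasonal-range checks use a ±5 % band rather than equality.

Growing degree days use base 10 °C over 1 April–31 October, daily mean
$(T_{min}+T_{max})/2$, negative contributions clamped to zero — standard
Winkler practice.

The half-sine irradiance profile
$I(t) = \frac{\pi S}{2\,DL}\sin(\pi t/DL)$ is the simplest shape that
conserves the daily total $S$ exactly; the daily canopy integral depends on
that total far more than on the shape. The default 48 sub-daily steps keep
the integration error well below 0.2 % (halving the step changes the result
by less than that, which a test asserts).

## Interpolation of weekly measurements

Vine description is measured roughly weekly; the engine needs daily values.
Continuous quantities interpolate piecewise-linearly, ramp from zero at
DAS 0 before the first observation, and hold after the last. Cluster count
steps at the nearest prior observation — counts do not interpolate.
Shoot trimming (at 86 DAS in the emulated trial) is represented purely by
the measurements flattening, never as an engine event: observed
trajectories drive the model.

## Calibration

`calibrate_scale()` fits one multiplicative factor on $P_{max}$ to measured
cumulative dry matter by least squares over [0.1, 10], using
`stats::optimize()` — Brent's method, i.e. golden-section search with
parabolic acceleration, appropriate because the objective is smooth and
unimodal in the factor. A single scalar keeps the calibration honest: with
weekly dry-matter data there is no information to separate $\alpha$, $K$
and $P_{max}$.

A precision caveat follows from the model's physics: because the light
response is partially saturated under the default parameters, seasonal dry
matter responds sub-linearly to $P_{max}$ (an elasticity well below 1), so
multiplicative noise on the dry-matter observations is *amplified* into the
recovered factor — noise-free observations recover the factor to better
than 1 %, but with realistic observation noise the recovered factor's
spread is roughly the noise level divided by that elasticity. The test
suite and the reproduction script measure the resulting recovery rates
directly rather than assuming calibration is better than the data allow.

## The sugar model

The package's downstream step is an ordinary least-squares regression of
measured °Brix on simulated cumulative dry matter between veraison and
harvest, and the use of that line to predict sugar under altered crop load.
Cluster number affects prediction only through cluster maintenance
respiration — the single crop-load pathway in the model — so predicted
Brix is pointwise non-increasing in cluster count whenever the cluster
respiration rate and the regression slope are positive. Per-berry dilution
(more clusters sharing the same assimilate changing berry-level
concentration directly) is *not* modelled; the scenario curves are
qualitative orderings, not enological predictions.

## Goodness of fit

`evaluate_fit()` reports $R^2$ (squared Pearson correlation — not
regression through the origin), MAE, RRMSE (RMSE over the observed mean)
and PBIAS $= 100\sum(O_i - P_i)/\sum O_i$. The PBIAS sign convention is
chosen so that a model that *under*-estimates a positive variable reports a
*positive* bias; published tables often print magnitudes only, so the sign
convention is stated here prominently.

## The synthetic-season generator

No field season is distributed, so the generator produces one with the
statistical structure the analysis assumes, from a single integer seed:

* **Weather** — daily mean temperature is a seasonal sinusoid (16.5 ±
  8.5 °C, centred on 20 July) plus AR(1) deviations (lag-1 coefficient 0.7,
  innovation sd 1.5 °C); the diurnal range fluctuates around 11 °C;
  radiation is 0.75 × extraterrestrial radiation × a Beta-sampled
  cloudiness in (0.15, 1]. For a 43.7° N site from 1 April this lands
  maximum temperatures in roughly 12–38 °C and radiation in roughly
  4–31 MJ m^-2^ day^-1^ — the ranges of a temperate vineyard season.
* **Canopy** — logistic growth of main leaf area and shoot surface
  flattening at trimming (86 DAS); light interception proportional to main
  leaf area, capped at 0.16 (VSP-like profile) or 0.18 (SHW-like); cluster
  fresh weight double-sigmoid from ~30 DAS to a profile cap (246 g vs
  300 g); constant cluster count (10.4 vs 9.8). The two named profiles
  differ exactly where a vertical-shoot-positioned and a single-high-wire
  canopy differ in published trials, so a two-treatment comparison can be
  re-enacted synthetically. One multiplicative factor per variable (sd 2 %)
  makes seasons differ without breaking monotone growth.
* **Observations** — cumulative dry matter sampled at 8 dates with 5 %
  multiplicative noise; °Brix at 10 post-veraison dates from a true linear
  relation (slope 0.019 °Brix g^-1^, intercept 2.8 °Brix) with 0.4 °Brix
  additive noise. The slope and intercept were set once so the synthetic
  must runs from ~16 °Brix at veraison (DAS 115) to ~23 °Brix at harvest
  over the default season's dry-matter span (~700–1100 g per vine) —
  typical technological-maturity numbers.

Each generator seeds its own stream (derived from the configuration seed)
and restores the caller's RNG state, so a season is one reproducible object
and generation never perturbs user code.

What the generator does *not* emulate: real weather autocorrelation beyond
lag 1, rain–radiation coupling, vine-to-vine spatial variation, measurement
dropout, and any feedback from crop load onto canopy growth. Tests passing
on synthetic seasons therefore demonstrate the pipeline's internal
correctness and statistical behaviour under the stated noise model — not
agreement with any particular field season.

## Numerical choices and degenerate inputs

* Latitudes beyond ±66° are rejected (polar day/night breaks the hour-angle
  formula).
* `light_interception = 1` is an error: it implies infinite leaf area under
  Beer–Lambert inversion.
* Zero observed variance or zero observed mean make $R^2$ or
  RRMSE/PBIAS undefined; `evaluate_fit()` refuses rather than returning
  NaN.
* Regression requires ≥ 3 points and non-constant dry matter at the
  sampled days.
* Default problem sizes in the test-suite Monte-Carlo sweeps (10–50 seeded
  replicates, 165-day seasons) were chosen to estimate pass rates with
  comfortable margins at sub-minute runtimes.

## Known limitations

Roots and trunk are not respiring pools (they are not inputs of the
emulated trial's model); there is no carbon partitioning, reserve dynamics,
water balance, or CO~2~-concentration response (ambient conditions are
implicit in $P_{max}$). The sugar model is strictly linear in per-vine dry
matter and inherits every limitation of that regression outside its fitted
range.

## A worked season

```{r example, eval = FALSE}
season <- generate_season(synthetic_config(seed = 42, profile = "shw"))
fit <- fit_brix_dm(season$brix_obs, season$sim)
fit
pred <- season$sim$dm_cumulative[match(season$dm_obs$das, season$sim$das)]
evaluate_fit(season$dm_obs$dm, pred)
autoplot(run_cluster_scenarios(season$weather, season$canopy,
                               carbon_params(), fit, c(6, 12)))
```
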