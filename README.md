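# frogphen

Mechanistic simulation of wood frog (*Rana sylvatica*) post-hibernation
emergence phenology, for ecologists studying how exogenous drivers
(meteorology, geography) and endogenous traits (behavior, morphology,
physiology) jointly set the timing of spring life-history events.

Wood frogs overwinter frozen in the topsoil, 2–5 cm below the litter, and
emerge in early spring to breed in vernal ponds. When they emerge is set by
an interplay of snowpack, soil thaw, air temperature, and behavioral
thresholds. `frogphen` couples a deliberately simplified below-canopy
microclimate model to a rule-based emergence model, and wraps both in the
statistical machinery needed to validate predictions against oviposition
surveys, build a climatological-normals null model, estimate decadal trends,
and attribute phenological variation to parameters along the
exogenous–endogenous gradient.

## The model

**Microclimate.** Daily weather (tmin, tmax, precipitation) is lapse-adjusted
(−6.5 °C km⁻¹), downscaled to hours by a piecewise sinusoid (minimum 05:00,
maximum 15:00) whose amplitude canopy damps by `1 − d·c` (cover `c`, damping
`d`). Precipitation partitions at a daily-mean threshold; snowfall is
intercepted by canopy (`1 − i·c`), accumulates as SWE, and melts by canopy-
damped degree-days `DDF · max(T̄, 0) · (1 − m·c)`, with exact mass balance.
Soil temperature obeys the 1-D heat equation `∂T/∂t = κ ∂²T/∂z²`
(backward-Euler on depth nodes, zero-flux bottom). Snow insulates: the
surface boundary is `w·T_air + (1 − w)·0 °C` with `w = exp(−depth/scale)` —
the subnivium effect in one parameter.

**Emergence rules.** A single frog per pond stays buried until, on some day:
the calendar has passed DOY 65; its body temperature (soil at the burrow
node, optionally with a mass-scaled thermal lag) has exceeded −0.16 °C —
the thaw inflection temperature — on three consecutive days; and the pond
has been snow-free for five consecutive days. It then emerges at the first
hour with a sufficient run of consecutive hours at or above its chosen
emergence air temperature (and below CTmax).

**Analysis.** Validation joins predicted emergence to egg-mass-weighted
survey dates per pond-year (RMSE/MAE, moving-window SDs, error GLM on 0–1
scaled covariates, PDSI drought filter); the null model replays each pond's
per-(DOY, hour) climatological normals; trends come from pooled OLS with
fixed pond intercepts and a case bootstrap; one-at-a-time (OAT) sensitivity
varies each parameter over {min, mean, max} while holding the rest at their
means, scoring importance as the range of interannual-mean emergence dates
and attributing it to parameter categories.

A synthetic-data module (seasonal + AR(1) daily weather with optional
warming trend, Bernoulli–Gamma precipitation, pond networks spanning canopy
0–0.9 near 236 m elevation, and survey records lagged behind emergence)
makes the whole pipeline testable without external forcing data.

## Worked example

```r
library(frogphen)

cfg      <- weather_config(seed = 42)                      # New England-like climate
weather  <- generate_daily_weather(cfg, n_years = 11, start_year = 2000)
ponds    <- generate_pond_network(8, canopy_range = c(0, 0.9), seed = 7)
config   <- run_config(2000, 2010, ponds)                  # first year is burn-in
emergence <- run_simulation(config, weather)
head(emergence, 3)
#>   pond_id year emergence_doy emergence_hour
#> 1     P01 2001            95              0
#> 2     P01 2002           110             20
#> 3     P01 2003           100              0

obs    <- generate_observations(emergence, lag_mean = 5, lag_sd = 2, seed = 9)
validate_emergence(emergence, obs)
#> <validation_report>
#>   80 matched pond-years (0 unmatched records dropped)
#>   RMSE 9.57 days, MAE 9.35 days
#>   mean 5-yr moving-window SD: predictions 7.28, observations 7.10 days

params <- default_parameter_table()
sim    <- oat_simulator(params, weather_config(seed = 42), n_years = 10)
oat    <- run_oat(oat_design(params), sim)
category_attribution(oat)
#>      category importance share_pct
#> 1 meteorology       68.2     58.64
#> 2   geography       17.0     14.61
#> 3    behavior       28.1     24.16
#> 4  morphology        0.0      0.00
#> 5  physiology        3.0      2.58
```

Predicted emergence lands on DOY ≈ 75–115 and varies by ~7–10 days across
years; validation error reflects the (here synthetic) emergence-to-
oviposition lag plus the weighted-survey pull; and attribution puts most
leverage on exogenous parameters, with behavior a moderate contributor and
morphology/physiology nearly inert.

A thin command-line wrapper over the same functions ships in
`inst/cli/frogphen.R` (subcommands `synth`, `simulate`, `nullmodel`,
`validate`, `trend`, `sensitivity`).

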