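---
title: "Methods: coupled microclimate and emergence phenology simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled microclimate and emergence phenology simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogphen)
```

`frogphen` simulates when wood frogs (*Rana sylvatica*) emerge from winter
hibernation, pond by pond and year by year, and asks how much of the
variation in that date is attributable to the environment versus to the
animal. This vignette is the package's own account of the model: what is
simulated, which simplifications were chosen and why, what the synthetic
data do and do not emulate, and where the numerical edges are.

## The calendar and the forcing

All phenology runs on a 365-day year (DOY 1–365, leap days dropped):
emergence is a day-of-year quantity and a fixed-length year keeps multi-year
hourly series rectangular. The forcing is daily minimum/maximum air
temperature and precipitation at a single site shared by every pond in a
network — the study system this emulates is a cluster of vernal ponds within
a few kilometres, inside one grid cell of a daily meteorological product, so
ponds differ in site descriptors (canopy cover, elevation, area) but not in
weather.

The synthetic generator (`weather_config()`, `generate_daily_weather()`)
builds the daily mean as

$$\bar T(y, d) = \mu + \beta\,(y - y_0) - A \cos\!\frac{2\pi (d - d_{\min})}{365.25} + a(t),$$

with an AR(1) anomaly $a_t = \phi\, a_{t-1} + \varepsilon_t$ parameterized
by its *stationary* standard deviation (so the configured `anomaly_sd` is
what a long series actually exhibits). `tmin`/`tmax` sit symmetrically
around the mean, which guarantees `tmax >= tmin` by construction. The
diurnal range is seasonally modulated (narrower in winter, wider in summer,
`diurnal_range_amplitude`, default 3 °C about a 10 °C base) — real
mid-latitude diurnal ranges are widest under clear summer skies, and without
this asymmetry the canopy's effect on annual maximum and minimum
temperatures would be artificially identical. Precipitation is
Bernoulli(`precip_prob`) × Gamma(`precip_shape`, `precip_scale`); the
defaults give ~900 mm yr⁻¹, a cool-temperate New England total.

Defaults (9 °C mean, 12.5 °C seasonal half-amplitude, coldest day DOY 25,
φ = 0.7, σ = 3.5 °C) were chosen once as a realistic southern New England
climate and are not tuned thereafter.

What the generator does **not** emulate: multi-site spatial correlation,
weather fronts and persistence beyond AR(1), rain-on-snow events as a
distinct process, and any covariance between temperature and precipitation
occurrence. Tests passing on this forcing therefore demonstrate the
*mechanics* of the pipeline and its invariants, not calibrated skill on real
meteorology.

## Below-canopy microclimate

`run_microclimate()` maps daily weather plus one pond's descriptors to an
hourly series of air temperature, snowpack, and a soil temperature profile.
It is a deliberately simplified analogue of a full radiative microclimate
model: radiation is never computed; canopy cover $c$ enters through exactly
three scalar pathways.

1. **Diurnal damping.** Hours are filled by a piecewise cosine with minimum
   at 05:00 and maximum at 15:00 (two segments, 10 h rising and 14 h
   falling, because the extremes are not 12 h apart). Canopy damps the
   departure from the daily mean by $1 - d\,c$ (default $d = 0.5$), so a 90%
   shaded pond keeps 55% of the open-site range.
2. **Snowfall interception.** Below-threshold (0 °C daily mean)
   precipitation becomes snowfall, scaled by `snowfall_multiplier`
   (microsites that collect windthrown snow), then reduced by $1 - i\,c$
   (default $i = 0.3$).
3. **Melt damping.** Degree-day melt $\mathrm{DDF}\cdot\max(\bar T, 0)\cdot
   (1 - m\,c)$ (defaults DDF = 3 mm °C⁻¹ d⁻¹, $m = 0.5$), capped at the
   available SWE.

Because $m > i$, shaded ponds accumulate less snow but hold it longer — the
canopy-interception pathway that orders spring emergence across ponds. Snow
mass balance is exact by construction and audited in the tests. SWE converts
to depth with a fixed 100 kg m⁻³ bulk density (the classical 10:1 ratio);
no densification is modeled.

**Soil.** The profile obeys $\partial T/\partial t = \kappa\, \partial^2
T/\partial z^2$ on nodes at 0, 2.5, 5, 10, 20, 50 cm by default — the 2–5 cm
frog burrow range is bracketed by nodes — with $\kappa = 4\times10^{-7}$
m² s⁻¹ (moist loam). Time stepping is backward Euler: unconditionally
stable at hourly steps on shallow nodes, and an M-matrix scheme, so interior
temperatures respect a discrete maximum principle (tested). The upper
boundary is pinned to $w\,T_\mathrm{air}$ with $w =
\exp(-\mathrm{depth}/\mathrm{scale})$ (default scale 10 cm): deep snow
decouples the soil from the air and pins the interface toward 0 °C, the
subnivium in a single parameter, rather than an explicit snow conduction
layer. On rain days the boundary is additionally nudged toward the
non-freezing rain temperature with weight `rain_absorption · rain/(rain+20)`
— a saturating, one-parameter stand-in for heat advected by infiltrating
rain, there so that soil moisture absorption is exercisable by the
sensitivity analysis. The bottom boundary is zero-flux. Elevation enters
only as a −6.5 °C km⁻¹ lapse adjustment relative to a 236 m reference.

The accuracy of the conduction scheme is checked against the analytic
damped-sinusoid solution $A e^{-z/D}$, lag $z/D$, $D = \sqrt{2\kappa/\omega}$
(≈ 10.5 cm for the diurnal cycle): on a 1-cm grid with 60 s steps the
simulated amplitudes sit within 1% and phases within 0.5% at 2–30 cm. The
check is confined to nodes well above the domain bottom because the analytic
solution is for a semi-infinite half-space; near an insulated bottom the
reflected wave roughly doubles the (tiny) local amplitude, which is a
property of the domain, not an error of the scheme. The default
six-node grid trades this resolution for speed in multi-decade runs; its
burrow-depth temperatures remain smooth, bounded, and correctly ordered,
which is what the emergence rules consume.

Initial soil temperature is 0 °C at all nodes; the slowest transient decays
with a ~12-day time constant, which is why the first simulated year is
always discarded as burn-in. What is *not* modeled: radiative transfer, soil
moisture potential and freezing, wind, humidity, and soil-property
heterogeneity.

## The frog

One frog per pond, fixed at its burrow depth (nearest soil node to
`burrow_depth`, default 3.5 cm → the 2.5 cm node) for the whole winter; no
within-winter vertical thermoregulation, feeding, energetics, mortality, or
movement. Body temperature is the burrow-node soil temperature, optionally
relaxed first-order with a time constant scaling as $(\text{mass}/11.6\,
\text{g})^{1/3}$. The default time constant is 0 (instantaneous
equilibrium — a 10 g buried animal tracks its substrate on sub-hourly
scales); the lag exists so that mass is exercisable as a morphological
parameter in sensitivity analysis.

Emergence requires, on the same day (`check_gating_conditions()`):

* DOY strictly past 65 (no observed activity earlier in the emulated
  region);
* daily *minimum* body temperature above −0.16 °C — the inflection
  temperature at which frog thawing begins — on 3 consecutive days;
* snow depth exactly 0 on 5 consecutive days.

Both windows are trailing and include the current day: the wording "for
*k* consecutive days" does not anchor the window, and current-day inclusion
is the weakest sufficient reading; it is centralized so the convention could
be flipped in one place. Evaluating thaw on the daily minimum is the
strictest sub-daily reading — it prevents emergence after a night that
refroze the burrow. "No snow" means exactly zero depth; there is no
partial-cover notion at a point site. Gating is evaluated daily (rule inputs
are day-scale quantities), while the release itself is hourly.

Once a day's gates pass, the frog emerges at the first hour whose running
count of consecutive hours with air ≥ `emergence_air_temp` (boundary
inclusive; default 5 °C) has reached `favorable_consecutive_hours` (default
12 h, the midpoint of the plausible 1–24 h range), provided air ≤ CTmax
(31 °C). The consecutive-hour counter runs across days — a warm night does
not reset it. The CTmax guard is the minimal quantitative reading of
"otherwise physiologically desirable" aboveground conditions; no humidity or
desiccation term is modeled. `simulate_frog_year()` is verified, on
hundreds of randomized pond-years, to agree exactly with an independent
exhaustive hour-scan that applies the rule definitions literally.

## Pipeline statistics

**Validation.** Oviposition surveys are collapsed to one observed day per
pond-year by an egg-mass-weighted mean of survey dates (all-zero counts fall
back to the unweighted mean, with a message; ties among surveys are
immaterial to a weighted mean). Predictions join observations by inner
join; unmatched records are counted, never imputed. RMSE and MAE of
`predicted − observed` are reported with per-pond breakdowns and trailing
5-year moving-window SDs of the network-mean series. Note the model
predicts *emergence* while surveys date *oviposition*: even a perfect model
shows a positive MAE equal to the mean lag, and the package's own
end-to-end test exploits this (a fixed lag L is recovered as MAE = L
exactly).

**Null model.** `climatological_null()` averages hourly air temperature
across years at fixed (DOY, hour) and averages the daily snow- and
rain-driving forcing at fixed DOY, then *recomputes* snowpack and soil
temperature on the averaged year — averaging snow depth directly would
manufacture physically impossible series such as perpetual trace snow, and
this recompute is the one place the two constructions differ. Because snow
and soil carry state across the calendar-year boundary, the averaged year is
spun up over three repetitions and the periodic steady-state year is
extracted; every emitted replicate is therefore bit-identical, and null
predictions have interannual variance exactly zero. On synthetic data with
interannual variability the null's validation RMSE exceeds the dynamic
model's, mirroring the degradation a dynamics-free predictor must show.

**Trend.** The decadal trend is pooled OLS of DOY on year with a fixed
intercept per pond, with a percentile case bootstrap (default 1000
iterations) for the CI. Under a common-slope, random-intercept data model
the fixed-intercept OLS slope estimates the same quantity as the
mixed-effects fit, so the package deliberately avoids a mixed-model
dependency in its core; random slopes are out of scope. Exact input
arithmetic is tested: a constructed series declining 0.16 d yr⁻¹ returns
−1.6 d decade⁻¹ to machine precision.

**Error regression.** OLS of errors on covariates min-max scaled to [0, 1]
(so coefficients are comparable across covariates of different units), with
percentile case-bootstrap CIs; constant covariates are dropped with a
warning since their scaling is undefined. Coefficients are always reported
on the scaled scale. Bootstrap coverage is verified by simulation
(≈ 95% ± 2 points over 1000 replicates). A drought filter
(`drought_filter()`) removes years with a user-supplied PDSI below −2.5;
PDSI itself is never computed.

## Sensitivity analysis

`oat_design()` builds one baseline run (all parameters at their means) plus
low/high runs per parameter — $2P + 1$ simulations, with the baseline
executed exactly once (tested with an execution counter against a naive
$3P$-run implementation). Importance is the range between the lowest and
highest of the three interannual-mean emergence dates, which captures
non-monotone responses (a {100, 90, 100} response scores 10, not 0).
Pond-years without emergence are excluded from the mean and counted; a
parameter whose runs never emerge is flagged rather than zeroed. Category
shares are each parameter's importance over the summed importance × 100 —
the only normalization under which per-category percentages and day totals
stay mutually consistent — and sum to 100 by construction.

OAT runs use a single reference pond whose canopy and elevation are
themselves rows of the parameter table (a single frog at a single location).
The default table covers three meteorological parameters (±2 °C offset,
0.5–1.5× precipitation, 0.5–1.5× snowfall), three geographic (canopy 0–0.9,
elevation 136–336 m, LAI 0–5), three behavioral (emergence temperature
1–10 °C, favorable hours 1–24, burrow depth 2–5 cm), one morphological
(mass 7.6–15.6 g) and two physiological (thaw threshold ±0.5 °C around
−0.16, thermal time constant 0–2 h). LAI is carried as a site descriptor
but has no effect pathway of its own (canopy cover is the single vegetation
control), so its importance is structurally zero. Mass acts only through
the thermal lag, so its leverage is near zero — which is itself the
scientific point the attribution makes: on this model, morphology and
physiology cannot move the emergence date much, while meteorology and
geography can.

`inflate_trait_ranges()` widens endogenous ranges about their means (scalar
factor, or explicit overrides such as stretching the favorable-hours range
from 1–24 h to 1–96 h) with clipping at physical floors.
`microclimate_sensitivity()` reuses the OAT machinery with the microclimate
itself as response (interannual mean annual min/max of hourly air and
topsoil temperature), restricted to exogenous parameters; a ±2 °C offset
passes through additively (importance exactly 4 °C), and canopy moves the
warm tail more than the cold one because summer diurnal ranges are wider.

## Problem sizes and determinism

Every stage is pure given (inputs, seed): weather generation is
bit-reproducible and restores the caller's RNG state; simulations contain no
randomness at all. The shipped tests run the soil oracle at 60 s/1 cm
resolution, snow mass balance over 1000 randomized years, oracle equivalence
over 200 randomized pond-years, the null/dynamic contrast on an 8-pond
decade, lag recovery at ~500 pond-years, and bootstrap coverage at 1000 ×
1000 resamples — sizes chosen so the full suite completes in a couple of
minutes while leaving each check statistically meaningful. The acceptance
script uses a 16-pond, 26-year study (25 analysis years, matching the
quarter-century observational window the synthetic study emulates).

## Known limitations

No radiation, soil moisture, or humidity; a single shared weather series per
network; snow as SWE with fixed density; one frog per pond with no
behavioral plasticity beyond the threshold parameters; oviposition timing
represented only as a stochastic lag on emergence. The sensitivity shares
are properties of *this* model's structure and parameter ranges — their
qualitative pattern (exogenous dominance, moderate behavior, inert
morphology/physiology) is the robust claim, not the percentages themselves.
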