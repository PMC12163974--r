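---
title: "Modelling Sphagnum net CO2 assimilation, canopy temperature and daily NPP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Sphagnum net CO2 assimilation, canopy temperature and daily NPP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphagnumflux)
```

## The problem

Sphagnum mosses dominate the carbon balance of boreal peatlands, yet their
net CO2 uptake responds to three tightly interacting drivers: the
temperature of the moss surface (not of the air above it), the water
content of the poikilohydric tissue, and irradiance. Because mosses lack
stomata, tissue water content tracks the environment, and because the
canopy sits millimetres above the peat, its surface temperature can depart
strongly from the meteorological air temperature under sunlight —
an effect that wet tissue buffers.

`sphagnumflux` implements a semi-empirical model of net assimilation built
from three components, the procedure that calibrates it from
dehydration-curve gas-exchange data, a canopy-temperature model that
downscales station meteorology to the moss surface, daily net primary
productivity (NPP) integration over half-hourly forcing, scenario
simulation (water table, warming, radiation, photoperiod, night
temperature) and parametric-bootstrap uncertainty propagation.

## The model

**Light response.** Net assimilation follows the Smith saturating light
response

$$A_N = \frac{(A_{sat}+R_D)\,\mathrm{PAR}\cdot\mathrm{AQE}}
{\sqrt{\mathrm{AQE}^2\,\mathrm{PAR}^2+(A_{sat}+R_D)^2}} - R_D,$$

with dark value exactly $-R_D$, asymptote $A_{sat}$, and initial slope
AQE (apparent quantum efficiency, default 0.0144 mol CO2 mol$^{-1}$
photons, measured at 25 °C and treated as temperature-invariant over
15–35 °C).

**Light-saturated assimilation.** $A_{sat}$ is a polynomial response
surface in moss temperature $T$ (°C) and water content $WC$
(g H2O g$^{-1}$ DW). The default *multiplicative* grouping is

$$A_{sat} = (a T^2 + b T + c)\,(-d\,WC^2 + e\,WC),$$

which (i) forces $A_{sat}\to 0$ as the tissue dries at every temperature
and (ii) gives a single temperature-independent water-content optimum
$WC^* = e/(2d)$ and temperature optimum $T^* = -b/(2a)$. An *additive*
variant $aT^2+bT+c-dWC^2+eWC$ is available through the parameter set's
`grouping` switch; every fit result records which grouping produced it.

The multiplicative product is invariant to reciprocal rescaling of its two
factors, so the five coefficients are not separately identifiable. We fix
the scale by requiring the temperature polynomial to equal 1 at its
vertex; `fit_asat_params()` fits the reduced form
$(1+\alpha(T-T_{opt})^2)(-d\,WC^2+e\,WC)$ and reports $a,b,c$ in that
normalised convention. Coefficients published in other conventions
describe the same surface but are **not numerically comparable** without
renormalisation — only scale-free summaries such as $e/(2d)$, $-b/(2a)$
and the surface values themselves transfer across conventions.

**Dark respiration.** $R_D$ follows a Heskel-form log-quadratic
temperature response with additive water-content terms:

$$R_D = e^{\,f + 0.1012\,T - 0.0005\,T^2} - g\,WC + h + i\,\ln(WC)\,T .$$

The exponent coefficients 0.1012 and −0.0005 are fixed global constants;
$f,g,h,i$ are fitted. We read the water-content terms as additive outside
the exponential: placing $h$ inside the exponent would make $f$ and $h$
jointly unidentifiable, and a multiplicative water factor would diverge as
$WC \to 0$, whereas the additive form crosses zero near complete
desiccation, which is what dehydration curves show. The logarithms here
and in the canopy model are natural by default (`log_base = "log10"` is
available and is recorded in all outputs).

**Canopy temperature.**

$$T_{moss} = T_{air} + j\,\mathrm{PAR}^2 + k\,\mathrm{PAR} + l + m\ln(WC),$$

a concave radiative warming term (interior maximum at $-k/(2j)$) buffered
by tissue water ($m<0$). The bundled reference set
`tmoss_params_hyytiala()` is the pooled field calibration
$0.017\,\mathrm{PAR} - 8.2\times10^{-6}\mathrm{PAR}^2 - 1.624\ln(WC) - 0.734$.
Because the model is linear in its coefficients given the regressors
$\mathrm{PAR}^2,\mathrm{PAR},\ln WC,1$, `fit_tmoss_params()` solves the
closed-form linear least-squares problem; the test suite verifies it
against hand-rolled normal equations and recovers the reference
coefficients from a noiseless grid to better than $10^{-8}$.

**Daily NPP.** Over a half-hourly forcing day,

$$\mathrm{NPP}_{day} = \sum_{00:00}^{23:30} A_N \cdot 1800 \cdot
\frac{44.01}{10^6} \quad \text{g CO}_2\ \text{m}^{-2},$$

per projected capitula area (not ground area). A constant flux of
1 µmol m$^{-2}$ s$^{-1}$ integrates to 3.80246 g CO2 m$^{-2}$, which the
tests assert.

## Calibration: the two-step procedure

Dehydration curves — gas exchange recorded while a rehydrated sample dries
inside the chamber — are processed record-by-record: water content from
fresh/dry weight, the IRGA humidity-dilution correction
$F = 9.73\times10^{-4}(\mathrm{H_2OS}-\mathrm{H_2OR})+1$, and the
corrected flux $A_N = \mathrm{flow}\,(\mathrm{CO_2R}-\mathrm{CO_2S}\cdot
F)/\mathrm{area}$ (flow converted from the instrument's µmol air s$^{-1}$
to mol air s$^{-1}$; all unit conversions live in `corrected_an()` and are
tested).

Calibration then runs in two independent steps:

1. `fit_rd_params()` fits $f,g,h,i$ to the dark dataset alone.
2. `fit_asat_params()` fits $a\ldots e$ to the light dataset through the
   full Smith composition with $f\ldots i$ and AQE **held fixed**.

Fixing the respiration coefficients prevents the much larger light dataset
from re-weighting the respiration fit. The suite verifies the steps are
independent: perturbing the light data never moves $f\ldots i$.

Both nonlinear fits use trust-region Levenberg–Marquardt with five starts
jittered ±50% around heuristic initials (cost tolerance $10^{-10}$, at
most $10^4$ evaluations): $f$ starts at the log mean dark respiration
minus the Heskel exponent at the mean temperature; the temperature
optimum and curvature start from a quadratic through per-temperature
maxima; the water-content parabola starts from the location and height of
the observed assimilation peak. Calibration fits the *raw* respiration
surface; prediction and NPP integration clamp $R_D$ at zero (night
respiration cannot be a CO2 sink), and $A_{sat}$/$A_N$ are never clamped —
negative assimilation at extreme temperature or desiccation is legitimate
model output. Goodness of fit is reported as the squared Pearson
correlation of observed vs predicted values.

## What the synthetic generators emulate

The package generates every input it consumes, from known ground truth:

* **Dehydration curves** at the study design's five chamber temperatures
  (15–35 °C) × five replicates × {dark, saturating 800 µmol m$^{-2}$
  s$^{-1}$}. Water content falls linearly from 17 g g$^{-1}$ at
  0.097–0.25 g H2O g$^{-1}$ DW min$^{-1}$ (interpolated across chamber
  temperature — hotter chambers dry faster), sampled every 5 min for up to
  2 h. Synthesis happens at the IRGA-reading level: Gaussian noise is
  added to the true flux (defaults 0.15 µmol m$^{-2}$ s$^{-1}$ in the
  light, 0.05 in the dark), then sample CO2 and humidity readings are
  solved so that processing reproduces that noisy flux exactly — so every
  end-to-end test also exercises the correction and flux equations. The
  default noise puts calibration $R^2$ near the 0.91–0.97 range.
* **Field observations**: covariates uniform over field ranges (air
  13–26 °C, PAR 0–1600, WC 1–17), surface temperature from the reference
  canopy model plus 1 °C noise.
* **Meteorology**: a July boreal diurnal cycle — air temperature on a
  piecewise half-cosine from the 12.4 °C night minimum at 03:00 to the
  19.4 °C maximum at 14:00 (a single sinusoid cannot place extremes 11 h
  apart, so rise and fall are separate half-cosines that hit both extremes
  exactly); PAR a half-sine over a 20.5 h photoperiod centred on noon,
  peaking at 750 µmol m$^{-2}$ s$^{-1}$, zero for the remaining 3.5 h.
  A 24 h photoperiod is treated as midnight sun (PAR floored at its
  half-step twilight value). Optional day-to-day temperature jitter;
  without it all days are identical.

What the generators deliberately do **not** emulate: instrument drift and
CO2 leakage, within-day water-content dynamics (no drying model exists for
the field scale; scenarios hold WC constant), fluorescence channels,
weather fronts or cloud stochasticity. Passing recovery tests on this
synthetic world therefore demonstrates that the estimation machinery is
correct and well-conditioned under the study design — not that the model
is an adequate description of any particular field dataset.

## Scenarios and uncertainty

`run_scenario_sweep()` covers five families: water-content sweep
(4.5–17 g g$^{-1}$) under unchanged forcing; air-temperature offsets
(±10 °C) and PAR scaling (0.6–1.6) at the species' optimum water content —
with the PAR factor applied to *both* the canopy warming term and the
light response, since radiation drives both; and square-wave days
(12/12, 18/6, 20/4 photoperiods; 25/15, 25/20, 25/25 °C day/night
temperatures at a 20/4 photoperiod) at saturating light, where set values
replace meteorological data. Results of the night-temperature family
default to the day/night triples above; other sweeps are user-configurable.

Uncertainty is propagated with a parametric bootstrap: each of 1000 draws
samples all thirteen coefficients $a\ldots m$ independently from normals
with their fitted means and standard deviations, holds the draw fixed
across every timestep of the period, and integrates NPP; the reported
uncertainty is the across-draw standard deviation of period NPP. Holding
draws fixed treats parameter uncertainty as fully time-correlated, which
is statistically coherent and conservative; a per-timestep variant
(averaging draws per half-hour record and summing the per-record standard
deviations over the period) is available behind `per_timestep = TRUE` for
comparison with aggregation schemes that treat records independently.
All randomness flows from explicit seeds; fixed seeds give bit-identical
results.

## Numerical choices and degenerate inputs

* Daily boundaries come from the forcing timestamps at local midnight;
  partial days and half-hour gaps are rejected with the offending
  timestamp named — never gap-filled or prorated.
* Rank-deficient calibration designs (single temperature, constant
  water content, collinear canopy regressors, constant humidity
  difference) raise explicit rank-deficiency errors rather than returning
  unstable estimates; light curves without curvature information trigger
  an ill-conditioned warning.
* Parameter standard deviations come from the Jacobian at the optimum
  ($\sigma^2 (J^\top J)^{-1}$, pseudo-inverse fallback when singular);
  the normalised $a,b,c$ standard deviations follow by the delta method.
* The dehydration-rate range is read as g (not mL) H2O g$^{-1}$ DW
  min$^{-1}$ — the only dimensionally plausible reading for a ~2 h curve
  spanning the measured water-content range.
* Zero crossing of assimilation along a drying curve is located by linear
  interpolation between the bracketing records; the assimilation maximum
  is reported at an observed record, without interpolation.

## Problem sizes

The test suite and analysis scripts run the full study design: 50 curves
(~1000 gas-exchange records) for calibration, 200 field observations,
14 forcing days, and 1000 bootstrap draws per scenario point — a few
seconds end to end, so there is no tension between fidelity and
practicality at this scale.

## Known limitations

* Field-fitted assimilation coefficients are not redistributable here;
  the bundled assimilation truth (`an_params_synthetic()`) is an
  explicitly synthetic stand-in (optimum WC 7.2 g g$^{-1}$, optimum
  25 °C, peak $A_{sat}\approx 2.6$ µmol m$^{-2}$ s$^{-1}$). Absolute NPP
  levels computed from it are internally consistent but not field
  estimates; its temperature polynomial is more strongly curved than
  field fits suggest, which depresses NPP under cool forcing.
* Water content is held constant within any NPP period; no dynamic
  drying/rewetting model is provided.
* No heterotrophic respiration, methane, ground-area upscaling or annual
  extrapolation: NPP is per projected capitula area over the simulated
  period only.
* Mechanistic (FvCB-type) photosynthesis and leaf energy balance are out
  of scope; the surfaces are empirical and should not be extrapolated far
  outside the calibrated covariate ranges.
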