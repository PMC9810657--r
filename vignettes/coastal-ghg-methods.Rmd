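---
title: "Methods: sea-air CO2/CH4 fluxes, greenhouse-gas budgets, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sea-air CO2/CH4 fluxes, greenhouse-gas budgets, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastalghg)
library(dplyr)
```

`coastalghg` turns continuous equilibrator/CRDS measurements of dissolved
CO2 and CH4 in shallow coastal waters into sea-air fluxes, daily and
seasonal integrals, and a net greenhouse-gas balance in CO2 equivalents.
This vignette explains the model behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The bulk flux model

The sea-air flux of a gas is computed from the partial-pressure
disequilibrium across the interface:

$$F = k \, K_0 \, (p_{\mathrm{sea}} - p_{\mathrm{air}})$$

with $k$ the gas transfer velocity (m s$^{-1}$), $K_0$ the volumetric
solubility (mol m$^{-3}$ atm$^{-1}$), and partial pressures in
$\mu$atm.  Positive fluxes are effluxes from the water to the
atmosphere.  Fluxes are reported in mg m$^{-2}$ d$^{-1}$ using molar
masses of 44.01 (CO2) and 16.04 (CH4) g mol$^{-1}$.

**Solubility.** Both gases use the classical temperature/salinity fit

$$\ln x = A_1 + A_2\,(100/T) + A_3 \ln(T/100) +
  S\,[B_1 + B_2\,(T/100) + B_3\,(T/100)^2]$$

with $T$ in kelvin.  For CH4 the fitted quantity $x$ is the Bunsen
coefficient $\beta$ and $K_0 = \beta/(R\,T_{\mathrm{STD}})$ assuming
ideal-gas behaviour ($R = 8.20573\times10^{-5}$ m$^3$ atm K$^{-1}$
mol$^{-1}$, $T_{\mathrm{STD}} = 273.15$ K); for CO2 the fitted quantity
is the volumetric solubility itself, each the native form of its
published fit.  Both gases expose the same `{beta, k0}` contract, with
the other member back-computed through the same ideal-gas relation.
Coefficients, their validity ranges, and the remaining gas constants
live in a versioned YAML file (`inst/extdata/gas_constants.yaml`) so
their provenance is auditable; out-of-range temperatures or salinities
raise an error naming the gas and the fitted range rather than
extrapolating.

**Schmidt number.** Fourth-order polynomials in temperature
(deg C) are evaluated for fresh water and for seawater at salinity 35,
then interpolated linearly in salinity:

$$Sc(S) = Sc_{\mathrm{fw}} + (Sc_{\mathrm{sw}} - Sc_{\mathrm{fw}})\,S/35 .$$

A literal product form of the brackish-water formula sometimes seen in
print is dimensionally inconsistent as an interpolation; since the
stated intent is interpolation between the salinity-0 and salinity-35
endpoints, the package implements the standard linear form.  Salinities
above 35 are refused rather than extrapolated.  The polynomial
coefficient sets are the widely used modern parameterization for which
CO2 in seawater at 20 deg C gives $Sc = 668$; the pinned coefficients
are recorded in the constants file.

**Gas transfer velocity.** The quadratic wind-speed parameterization

$$k = 0.251\, U_{10}^2\, (Sc/660)^{-1/2}$$

yields $k$ in cm h$^{-1}$ (the native unit of the 0.251 coefficient);
the package stores both cm h$^{-1}$ and the m s$^{-1}$ value used in the
flux equation, making the unit conversion explicit rather than
implicit.  Winds measured at sensor height $z_u$ are first adjusted to
10 m assuming a neutral logarithmic profile,
$U_{10} = U + (u^*/\kappa)\ln(10/z_u)$ with $\kappa = 0.4$; "log" is
the natural logarithm, as in the underlying profile theory.  The
formula can produce negative values for sensors above 10 m; these are
clamped to zero with a warning.

**Partial pressures.** The analyzer reports dry mole fractions, so
$p = x_{\mathrm{ppm}} \times P_{\mathrm{tot}}$ with total pressure from
the environment file (default 1 atm) and no water-vapour correction —
the measured stream is dried.  The pressure default is configurable.

## Quality control of the raw stream

A deployment alternates 35 min of water-equilibrated headspace with
10 min of ambient air (45-min cycles), logged every 10 s.  The QC chain:

1. **Cycle parsing** groups records into habitat deployments and pairs
   each water run with its following air run; windows are half-open
   `[start, end)`. Truncated cycles are flagged `partial`, oversized
   ones `irregular`; a leading air run has no parent water window and
   its records become orphans.
2. **Transition purging** flags records within `purge_s` (default
   300 s) of any phase or station switch.  The analyzer's e-folding
   response to the concentration step at a switch is of order a minute;
   five time constants reduce the residual to below instrument noise,
   which motivates the 300 s default.  The purge is configurable
   because the true response time depends on the equilibrator plumbing.
   Records flagged `malfunction`/`low_flow` stay excluded.
3. **Atmospheric reference**: each cycle's purged air-window mean is the
   reference $p_{\mathrm{air}}$ for the adjacent water window — the
   nearest-in-time atmospheric measurement.  Cycles with an unusable
   air window produce missing fluxes rather than borrowing references
   across cycles.
4. **Environment join**: nearest-neighbour in time, refusing matches
   beyond `max_gap_s` (default 15 min).
5. **Averaging**: fluxes are averaged to clock-aligned 15-min intervals
   and then to daily net fluxes (mean of the day's interval means; the
   units are already per day, so no rescaling).  The daily standard
   error is computed from the spread of the 15-min means, not the 10-s
   records, to avoid the serial-correlation underestimate that raw
   records would produce.  Days with less than `min_coverage` (default
   50%) of their 15-min slots are reported missing with a reason.
   Diel composites bin the 15-min means into twelve 2-hour blocks of
   local clock time (`[00:00, 02:00)` is bin 0); campaigns use the
   local clock with no DST shifts.

## Budgets and CO2-equivalent accounting

Seasonal campaign means extrapolate to an annual cumulative flux as
$\sum_s \bar F_s L_s / 1000$ g m$^{-2}$ y$^{-1}$, with season lengths
$L_s$ defaulting to a quarter year (91.3125 d) each — the campaigns
sample four seasons but do not define calendar boundaries, so equal
quarters are the neutral choice and per-season overrides are accepted.
Seasonal errors propagate as independent,
$\sqrt{\sum_s (se_s L_s)^2}/1000$, because the campaigns are distinct
deployments.

CH4 is converted to CO2 equivalents with the sustained-flux global
warming potential, SGWP = 45 (mass basis, 100-year horizon), because a
coastal ecosystem exchanges gas continuously rather than as a one-time
pulse; the pulse GWP is deliberately not implemented, and the factor is
data (in the constants file), not code.  The net balance is
$F_{\mathrm{CO_2}} + 45\,F_{\mathrm{CH_4}}$; when CO2 is taken up the
offset percentage $100 \times 45 F_{\mathrm{CH_4}} / |F_{\mathrm{CO_2}}|$
says how much of the sink is counterbalanced, and when CO2 is emitted
the same ratio is an augmentation.  Reporting rounds to integer grams
and percent; full precision is kept internally.

```{r balance}
balance_table(ghg_balance(
  f_co2 = c(-52, -71, 30), f_ch4 = c(0.34, 0.55, 0.38),
  habitat = c("macroalgae", "mixed_vegetation", "bare_sediment")
))
```

Note the macroalgae row: from the rounded annual inputs (-52, 0.34) the
arithmetic gives -37 g CO2-eq and a 29% offset; reports computed from
unrounded source data can differ by one unit in the last digit.

## ANOVA and Tukey HSD from summary statistics

Published comparisons often provide only mean, SD and n per group.  The
package reconstructs the one-way ANOVA (`MSB`, `MSE`, F) and Tukey HSD
simultaneous intervals exactly from those moments; the result is
provably identical to the raw-data computation for any dataset sharing
them, a property the test suite checks against `stats::aov()` +
`TukeyHSD()` on randomly generated raw data.  Studentized-range
quantiles come from R's `qtukey`.  Pair direction follows the declared
input order (difference = second minus first); published tables mix
sign conventions, so the caller chooses the order and the documentation
says so.  When `MSE = 0` with distinct means, F is reported infinite
with a flag rather than `NaN`.

```{r tukey}
groups <- tibble::tibble(
  label = c("macroalgae", "open_water_1", "open_water_2"),
  mean = c(56.69, 50.41, 49.73), sd = c(0.76, 1.48, 2.48),
  n = c(70, 105, 119)
)
tukey_hsd_from_summaries(groups) %>%
  select(group_a, group_b, difference, ci_low, ci_high)
```

**Oxygen penetration depth** is the shallowest depth at which the O2
concentration of a 100-$\mu$m-resolution microprofile drops below
1 $\mu$M and stays below it.  A single sub-threshold point can be
sensor noise, so the default requires 3 consecutive sub-threshold
points (300 $\mu$m); a sub-threshold run that reaches the end of the
profile also qualifies, since a profile that ends anoxic cannot recover.
Both threshold and persistence are arguments.

## The synthetic-data generator and what it validates

Real campaign streams are not redistributable, so the package ships a
seeded generator that emulates the whole observation chain:

* **Environment** (1-min resolution): water temperature with a weak
  diel cycle; salinity drawn uniformly in 6.6-7.0 (brackish, as at the
  study sites); wind from a Weibull distribution (shape 2, scale
  5 m s$^{-1}$ by default) given hour-scale persistence through an
  AR(1) transform — no wind statistics are published for the site, so
  a textbook coastal wind climate is used; friction velocity from a
  constant drag coefficient; pressure 1 atm.
* **Gas truth**: pCO2 follows a sinusoidal diel cycle whose minimum
  (peak uptake) sits at 15:00, inside the observed 13:00-17:00
  afternoon window; CH4 is a persistently supersaturated concentration
  (tens of nmol L$^{-1}$) converted to partial pressure through the
  solubility, so CH4 is always an efflux.  Both carry AR(1) noise.
  Wind and pCO2 are generated independently; their real
  cross-correlation is unknown, and coupling them would presume a
  mechanism the data cannot confirm.
* **Observation process**: 35/10-min cycles logged at 10 s, a
  first-order response lag (time constant 60 s) after each phase
  switch, and additive Gaussian instrument noise (0.5 ppm CO2,
  0.001 ppm CH4, typical of a CRDS at 10-s averaging).
* **Truth ledger**: per-minute p_sea, p_air, k, K0 and the flux
  computed from them exactly; trapezoid-integrated true daily fluxes;
  true cycle boundaries; the index of lag-contaminated records.  All
  randomness flows from a single seed, so campaigns are byte-identical
  under a fixed seed.

The six presets (four seasons for the macroalgae habitat; summer for
the mixed-vegetation and bare-sediment habitats) are calibrated so the
true daily fluxes land inside the per-habitat seasonal ranges reported
for the study region (CH4 0.1-2.9 mg m$^{-2}$ d$^{-1}$ depending on
habitat; CO2 between roughly -763 and +390 mg m$^{-2}$ d$^{-1}$).
These are calibration envelopes, not fitted distributions: the presets
reproduce magnitudes and qualitative structure (seasonality, diel
phase, supersaturation), not the empirical joint distribution of the
field data.  Validation on synthetic campaigns therefore demonstrates
that the pipeline recovers known daily fluxes without bias under a
realistic observation process — it does not certify accuracy on real
data, where equilibrator response, sensor drift and footprint issues
are messier than the generator's idealizations (no tides are simulated;
the sites are non-tidal).

The recovery experiment used in validation runs 100 one-day campaigns
per preset (a scale chosen to give the bias test useful power while the
whole suite stays fast), requires 95% of days within 2 SE of ledger
truth, and tests the mean error against a 99% Monte-Carlo interval.

```{r recovery}
rec <- recover_campaign(scenario_config("macroalgae-summer", seed = 42))
rec
```

## Numerical choices and degenerate inputs

* Half-open intervals everywhere (cycle windows, averaging intervals,
  diel bins) so records are never double-counted.
* Interval means use only ok-flagged records; empty interior intervals
  are emitted as explicit missing rows, and a single-record interval
  has SD 0 (not NA) so downstream weighting stays defined.
* `NA` gas readings propagate to `NA` fluxes; they are missing records,
  not errors.
* The purge must be shorter than the shortest phase window, otherwise
  the configuration is rejected outright.
* Negative 10-m wind adjustments clamp to zero with a warning (the
  logarithmic profile is not meaningful there).
* Studentized-range quantiles are accurate to well below $10^{-4}$
  (R's implementation); the two-group case collapses to the pooled-t
  interval, which the tests verify as an identity.

## Known limitations

* Only the wind-speed-squared transfer-velocity model is implemented;
  current- or depth-driven estuarine parameterizations are out of
  scope, as are bubble-mediated transfer and eddy-covariance fluxes.
* Annual budgets are first-order extrapolations of four seasonal
  campaigns; they carry no within-season trend model.
* The CO2-equivalence accounting stops at the fixed-horizon SGWP; no
  radiative-forcing time integration, no N2O, and no burial/export
  carbon accounting.
* The summary-statistics ANOVA assumes homogeneous variances (pooled
  MSE), matching the classical Tukey procedure; no Welch-type
  adjustment is provided.
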