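---
title: "Modelling fleet emission scenarios and their health impacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fleet emission scenarios and their health impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleetair)
```

## What the package models

`fleetair` is a bottom-up model of the tailpipe CO2 and NOx emissions of a
national passenger-vehicle fleet under contrasting policy scenarios, with a
downstream life-table estimate of the mortality benefit of the resulting NO2
reductions. The chain is:

1. **Vehicle records to segment profiles.** Each vehicle model carries its
   registrations, EURO market segment, fuel class, masses, engine capacity,
   wheelbase, type-approval CO2 (g/km) and on-road NOx (mg/km). The SUV (J)
   segment is split by kerb mass into small (< 1500 kg), medium (1500–2000 kg,
   boundaries inclusive) and large (> 2000 kg). Annual per-model emissions are
   `C·R·D/10^6` tonnes of CO2 and `N·R·D/10^9` tonnes of NOx, where `D` is the
   fuel-class annual distance (petrol family 10,137 km, diesel family
   15,125 km, battery-electric 15,180 km). Segment means (total emissions over
   vehicle count) are the per-vehicle rates used by all projections.
2. **Regressions.** Ordinary least squares characterises how emissions scale
   with vehicle mass: CO2 on test mass, engine capacity, wheelbase and a
   diesel indicator over all internal-combustion records; NOx on mass and
   engine capacity, separately per fuel family. Inference is classical
   (homoskedastic, t-based intervals).
3. **Stock turnover.** A survival schedule `S(a)` gives the fraction of a
   sales cohort still in service at age `a`, calibrated below.
4. **Scenarios.** Five presets: business as usual; replacement of medium and
   large SUV sales by small SUVs (1:1); replacement of all SUV sales by
   B/C/D-segment cars (1:1); electrification (battery-electric sales share
   25% in 2025, 70% in 2030, 100% from 2035, interpolated linearly, residual
   sales petrol plug-in hybrid over 2030–2035); and electrification combined
   with the small-SUV substitution, substitution applied first.
5. **CO2 accounting.** Cumulative emissions of all post-policy cohorts to a
   horizon (2035, 2050), each cohort-year weighted by `S(age)`.
   Battery-electric vehicles emit through charging: energy used
   (distance/efficiency) times the grid carbon intensity of the calendar
   year. Savings versus business as usual are valued at marginal abatement
   cost prices (low/central/high per horizon).
6. **NOx and NO2.** Whole-fleet NOx adds a legacy fleet — pre-policy cohorts
   emitting at the regulatory limit of their registration era — to the
   post-policy cohorts at base-year per-vehicle rates. Fleet NOx relative to
   business as usual scales the passenger-car share of urban background NO2,
   2.59 µg/m³, proportionally; the reduction is clamped to `[0, 2.59]`.
7. **Life table.** The NO2 reduction series modifies all-cause mortality
   hazards at ages 30+ through `RR = 1.023^(-Δ/10)` (95% CI 1.008–1.037),
   phased in by a distributed inception lag. Person-years of the impacted
   minus the baseline projection, accumulated to 2126, are the life years
   gained, valued at a discounted value per life year (default GBP 60,000 at
   1.5%/year).

## Calibrating the survival schedule

The schedule is pinned by four kinds of printed constraint: `S(0) = 1`;
`S(14) = 0.5` (median lifespan 14 years); `S(25) = 0`; and steady-state fleet
coverages of a post-policy sales stream — 41% of the on-road fleet covered
five years after policy start, 77% after ten, 96% after fifteen, where
coverage at age `y` is `Σ_{a≤y} S(a) / Σ_a S(a)`.

The construction interpolates cumulative coverage linearly between milestone
ages, which makes `S` constant within each span. The median constraint fixes
the stock scale: with `S = 0.5` across ages 11–15,
`W = Σ S(a) = 0.5·5/(0.96-0.77) ≈ 13.16` expected service years, comfortably
consistent with a 14-year median. The tail (ages 16–25) declines linearly to
zero while holding the remaining 4% of stock.

These constraints are, however, jointly over-determined: meeting the age-5
coverage of 41% exactly while starting at `S(0) = 1` would force the implied
retention to *rise* between ages 1–5 and 6–10 (0.879 vs 0.947), which no
survival curve allows. A proof sketch: the first six ages sum to `0.41·W` with
`S(0)=1`, capping `W ≤ 14.6`, while requiring every age-1–5 value to be at
least the age-6–10 mean forces `W ≥ 20`. The calibration therefore pools the
two offending spans (a pool-adjacent-violators step), preserving the age-10
and age-15 coverages *exactly* and approximating the age-5 coverage (achieved
0.423 vs 0.41). `print()` on the schedule reports achieved versus requested
coverage, and genuinely infeasible milestone sets (pooled retention above 1,
or a tail that cannot stay monotone) are rejected with diagnostics.

```{r schedule}
calibrate_survival()
```

## What the synthetic data emulates — and what it does not

No vehicle registration extract or national population table ships with the
package; a synthetic-data module generates inputs with the right statistical
structure so every stage runs end to end.

**Fleet.** 181 vehicle models carrying 1,560,452 registrations are allocated
to the observed base-year segment × fuel composition (40.2% SUV, 61.5% petrol,
20.3% diesel, 4.7% battery-electric). Kerb mass is uniform within
segment-specific ranges chosen so the SUV sub-classes land in their defining
bands; engine capacity and wheelbase derive from the same latent size factor
plus independent noise, mimicking the collinearity of real fleets
(mass–engine–wheelbase all grow together). CO2 and NOx come from the fitted
linear models — CO2: `181.546 + 0.1028·mass + 0.0198·engine −
0.0793·wheelbase − 24.366·diesel`; NOx: `−57.04 + 0.0677·mass +
0.0299·engine` — plus Gaussian noise, floored at zero; battery-electric
records get zero emissions and zero engine capacity. The noise standard
deviations (11.5 g/km, 35 mg/km) were calibrated once so refitted regressions
reproduce the published explanatory power (CO2 R² ≈ 0.886; diesel NOx
R² ≈ 0.5) and then frozen. Registrations come from a single multinomial draw,
so the grand total is conserved exactly while per-cell counts vary across
seeds. One seed drives every draw.

Deliberate simplifications: hybrids and plug-in hybrids draw from the same
linear emission models as other internal-combustion records (keeping the
regression recovery unbiased), although real plug-in type-approval CO2 values
are far lower; every internal-combustion model has an on-road NOx value,
whereas the real data covered only ~60% of registrations; and the model list
is not the real one. Consequently, passing tests demonstrate that the
*procedures* are correct under the stated generating process — not that the
synthetic fleet reproduces the real fleet's absolute emission totals.

**Population.** A stationary population by sex and single year of age 0–105
under a two-parameter Gompertz-type schedule (annual force of mortality
`h0·e^{b·age}` converted to probabilities via `1 − e^{−h}`), with 700,000
births per year split evenly. Defaults give life expectancies of roughly 84
(female) and 80 (male) years. Deaths are deterministic (population × hazard),
so observed hazards reproduce the configuration exactly. There is no infant
or accident hump and no cohort trend, so absolute life-year totals are
indicative, not national estimates. On ingest, hazards for ages 90+ are
pooled to the group's aggregate, and a hazard of 1 or more at any age is
rejected naming the age.

## Numerical and accounting conventions

- **Charging emissions.** Annual per-vehicle charging CO2 is
  `(distance/efficiency) × intensity / 10^6` tonnes — energy times carbon
  intensity, the only dimensionally consistent reading. The default grid
  trajectory is piecewise linear through (2020, 180), (2025, 100), (2030, 40),
  (2035, 5), (2050, 2) g/kWh — a power sector nearly decarbonised by the
  mid-2030s. A slower, linear-to-2050 decline makes charging erode over 6% of
  the electrified scenarios' 2050 savings, contradicting the under-1% erosion
  the model is meant to exhibit; the fast default keeps it at ~0.97%,
  measured as (savings excluding all charging − savings including it) over
  the former, charging in the baseline counted too. The trajectory is fully
  overridable.
- **Attrition everywhere.** Cumulative totals weight every cohort-year by the
  surviving fraction, for combustion and electric vehicles alike (rather than
  giving electric vehicles a flat 14-year life), and count emissions through
  the end of the horizon year inclusive.
- **Legacy fleet.** Default: constant historical sales of 2.5 million/year
  over 1995–2019 with a 45% diesel share, emitting at bundled regulatory
  limits (diesel 900/500/250/180/80 mg/km for pre-2001/2001/2006/2011/2015+;
  petrol 500/150/80/60 for pre-2001/2001/2006/2011+), both overridable. Under
  these stylised assumptions whole-fleet NOx falls steeply through 2030 and
  then flattens — new cohorts at base-year on-road rates (~1.1 kg/vehicle)
  emit about as much as the surviving newest legacy tiers — so the fleet
  total's strict decline is asserted through 2030, with 2035 well below 2020,
  and all the way down only for the electrified scenarios.
- **Life table.** End-of-year convention: each simulated year the population
  ages one year, newborns enter at age 0, the (possibly risk-scaled) annual
  death probability of the attained age applies, and person-years accrue as
  the end-of-year population. The relative risk multiplies the annual death
  probability directly; at these magnitudes the rate/probability distinction
  is immaterial. A modified probability above 1 is an error, not a clamp.
  Discounting references the policy start year (2020). The inception lag
  phases each year-on-year increment of the reduction in independently (30%
  after one year, full after 20); the NO2 series is held at its last value
  beyond the projection window. Births continue to 2126; cohorts born after
  2096 never reach age 30, so their baseline and impacted person-years cancel
  exactly and including them does not change the estimate.
- **Degenerate inputs.** Rank-deficient regression designs are rejected
  naming the collinear columns (an all-zero predictor is never silently
  dropped); empty segments are omitted from profiles with a warning, never a
  silent zero; a missing regulatory limit or emission rate names the
  offending fuel-year or cell.

## Problem sizes and runtime

The default end-to-end run — 181 models, five scenarios, CO2 to 2050, fleet
NOx over 2020–2060, two-sex life tables over 2020–2126 and a 12-cell
sensitivity grid — completes in well under a minute on a single CPU. The test
suite's oracle comparisons use the same sizes; the parameter-recovery check
averages 20 generated fleets.

## Known limitations

Absolute cumulative totals under the substitution scenarios are much smaller
than the corresponding published headline figures; the published small-SUV
column is not derivable from the published per-vehicle and composition
tables under a 1:1 substitution, so those absolutes serve as reference
values, not targets, here. Embedded and non-tailpipe emissions, particulate
matter, rebound effects, demand elasticity, collision risk and hydrogen
vehicles are all out of scope. NOx maps to NO2 by direct proportionality with
no atmospheric chemistry, and the legacy fleet is treated as purely
combustion-powered.
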