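---
title: "codibm: model structure, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codibm: model structure, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codibm)
```

This vignette documents the simulator's scientific content: the annual
cycle, every tunable parameter group with units and rationale, the
calibration procedure, the numerical and design choices made where the
design was genuinely open, and the limitations a user should keep in mind
before reading ecological conclusions off desk-scale runs.

## The population and the annual cycle

The unit of simulation is the individual fish: age (1–20 yr), length
(cm, structural, never shrinking), somatic weight (kg, tied to length by
`W = k_cond L^3` with `k_cond = 1e-5` kg/cm³, i.e. condition factor 1.0
in g/cm³ units), gonad mass (kg, rebuilt each year), maturity state, and
two traits carried both as genetic values and as phenotypes (genetic
value plus a lifelong environmental deviation drawn at recruitment).

Each model year runs, in this order:

1. **Density dependence.** Food availability is
   `a(B) = 1/(1 + B/B_half)` with `B` the total start-of-year biomass.
   `B_half` (default 20 000 kg at desk scale) sets how strongly a crowded
   population raises the effort cost of feeding.
2. **Foraging and the oxygen cap.** The appetite phenotype multiplies an
   allometric intake baseline `I0 · W^0.7` (J/yr); desired effort is
   `appetite / a(B)`. Effort is capped at `effort_cap = 6` and by the
   largest aerobically sustainable effort, the solution of
   `SMR · (1 + c_act · e) = o2_max · q_oxycal`. Realized intake is
   proportional to effort, so a capped fish eats less than it wants.
3. **Metabolism.** `SMR = c_SMR W^{0.7} Q10^{(T-4)/10}` with `Q10 = 2`;
   activity costs `c_act = 0.35` of SMR per unit effort. Oxygen demand is
   metabolised energy over the oxycalorific coefficient
   `q_oxycal = 13.6` J/mg O₂ (the standard fish-physiology constant).
   Maximum uptake is `c_MMR W^{0.7} g(T)` with a Gaussian dome
   `g(T) = exp([(4-13)^2 - (T-13)^2] / (2·6^2))` normalised to 1 at 4 °C
   and peaking at 13 °C. Over 4–12.4 °C the dome rises faster than the
   SMR Q10, so aerobic scope widens with warming — the mechanism by which
   a cold-edge stock benefits from moderate warming — and tightens as the
   warmest scenario approaches the dome peak.
4. **Allocation and growth.** Net energy goes entirely to soma when
   immature; mature fish allocate
   `r = min(r0 + k_r · years post maturation, r_cap)` (0.25, 0.10/yr,
   0.80) to gonads. The rising ramp concentrates egg production in old,
   large fish, which is what makes a fishery that targets large fish
   demographically consequential. Negative net energy is paid from soma
   (weight loss, length retained); a fish whose weight falls below
   `0.4 · k_cond L³` dies of starvation. Somatic and gonad tissue both
   cost `5e6` J/kg.
5. **Maturation.** Immature fish run a Bernoulli trial on the PMRN:
   `p = logistic((L - Lp50)/s_w)`, `Lp50 = intercept + slope · age`,
   slope `-2` cm/yr, envelope width 20 cm between the 25% and 75%
   contours (`s_w = width / (2 ln 3)`). Only the intercept evolves;
   slope and width are fixed population constants. Maturity is absorbing.
6. **Mortality.** Six additive instantaneous components; survival is
   `exp(-ΣZ)`: fixed (0.02/yr); predation
   `0.12 (L/50)^{-1.6} + 0.008`, declining with size to a floor;
   foraging, the predation rate times `0.06 · effort^{1.5}` (risk taken
   while feeding); reproduction `0.3 · GSI^{1.5}`; respiration
   `0.25 · usage^5`, negligible with ample aerobic scope and steep near
   the ceiling; and fishing `F_max · U(L)`. Each year every fish is
   independently assigned trawl (70%) or gillnet (30%) exposure. Both
   gears share the Gaussian selectivity around `L_max = 110` cm with
   `σ = 0.28 L_max = 30.8` cm; the trawl is 1 above `L_max`. Conditional
   on death, a single categorical draw proportional to the component
   rates attributes the cause for the mortality-decomposition logs.
7. **Reproduction.** Surviving mature fish spawn: eggs are gonad energy
   over `egg_energy = 5` J/egg (a 1 kg gonad ≈ 10⁶ eggs). Expected
   recruits follow Beverton–Holt `R = αE/(1 + E/β)` and the realized
   count rounds stochastically (floor plus Bernoulli on the fraction) to
   avoid systematic bias. Each recruit draws two parents independently,
   with replacement, with probability proportional to gonad mass
   (self-pairing is allowed, keeping single-survivor years well
   defined). Traits are midparent values plus Gaussian inheritance noise,
   truncated to positive support; phenotypes add an environmental
   deviation. Recruits enter the next year at age 1 (18 cm) and are not
   exposed to mortality in their natal year.
8. **Ageing.** Survivors age; fish beyond age 20 die; the
   years-post-maturation counter advances for previously mature fish so
   a newly matured fish allocates at `r0` in its first spawning year.

This ordering (forage → grow → mature → die → reproduce) makes the
current year's gonads determine both reproductive mortality and parental
weighting, and lets newly matured fish first spawn the following year.

## Heritability calibration

Inheritance noise is `inh_sd` per trait (0.03 for appetite, 2 cm for the
PMRN intercept); under midparent transmission the equilibrium genetic
variance without selection is `2 · inh_sd²`. Environmental deviations are
`env_sd = 2·sqrt(2) · inh_sd` (0.085 and 5.66 cm), which fixes the
expected midparent–offspring regression slope at
`V_G / (V_G + V_E) = 0.2`. The *emergent* value under selection is what
`heritability_report()` measures on the engine's per-recruit log.

One estimator subtlety: pooling recruitment events across hundreds of
years of a drifting or evolving population adds a shared cohort
covariance — yearly parental-pool means move with density and selection,
and offspring cohort means move with them — which inflates the naive
pooled slope far above the transmission value (we observe ~0.5 for
appetite). `estimate_heritability()` therefore accepts a grouping factor,
and `heritability_report()` centres both variables within
year × replicate (year fixed effects) so the slope measures transmission.
With the default variances the emergent value is 0.19–0.21 for both
traits across seeds, comfortably inside the 0.15–0.25 band expected for
life-history traits.

## Climate scenarios

The mean trajectory is a saturating exponential
`T(y) = T_inf - (T_inf - T0) exp(-3y/ramp)`, reaching 95% of the warming
at `ramp` years: smooth, monotone, and consistent with stabilisation
"within 100–500 years". Defaults: `T0 = 4` °C everywhere; asymptotes
4.8/7.0/12.4 °C and ramps 100/250/500 yr for SSP1/SSP2/SSP3; the baseline
holds 4 °C, so the SSP3 total increase is 8.4 °C. Interannual noise is
i.i.d. Gaussian with SD 0.5 °C (the published trajectories show
variability bands without printing a value; 0.5 °C gives visually similar
bands), switchable to 0 for bit-reproducible runs.

## Desk scale, spin-up and what the defaults were tuned for

The reference stock's initialisation (5000 years, ~120 000–330 000
individuals) is far beyond what a test suite should run, so the default
parameterisation is **desk scale**: the `scale` argument of
`cod_params()` multiplies `B_half` and `bh_beta` jointly, preserving
per-capita dynamics while setting absolute numbers. At `scale = 1` a
500-year spin-up at `F_max = 0.2` and 4 °C equilibrates near 2400–2500
individuals (~24 t) — the "≈2000 individuals" scale used throughout the
tests and the acceptance script, with 300-year, 20-replicate scenario
experiments.

The free mortality/recruitment constants were calibrated, at this scale,
for: a stable spin-up; natural mortality declining with size; viable
populations in all four scenarios crossed with `F_max ∈ {0, 0.2, 0.3}`;
maturation near ages 4–6 declining with fishing pressure and rising with
warming; and an unfished equilibrium exceeding the fished one. On the
last point desk scale compresses the contrast: the reference
configuration shows an unfished/fished-at-0.2 abundance ratio near 2.7,
while here density-dependent food release strongly buffers a small
population's egg production (fishing frees food, survivors fatten, egg
output partially recovers), and pushing the recruitment parameters far
enough to counteract that buffering makes the warmest scenario and
`F_max = 0.3` populations collapse. The shipped defaults keep every
treatment viable and yield a ratio of ~1.3–1.5; the direction is robust,
the magnitude is scale-dependent.

## Numerical and degenerate-input choices

- Energy books balance exactly: realized intake = metabolism + soma +
  gonads + starvation deficit, to 1e-9 relative, per individual-year.
- The oxygen cap is enforced by construction (effort is solved from the
  budget), so `usage_ratio ≤ 1` up to floating-point rounding.
- An empty population is a valid state: the year logs zeros and the run
  continues (extinction is an outcome, not an error); spin-up aborts
  with a diagnostic instead, since its contract is to produce a snapshot.
- Years with no eligible parent (no positive gonad mass) produce zero
  recruits; a lone spawner may serve as both parents.
- Trait truncation at positive support protects the logistic and
  allometric forms from zero/negative traits; with the default variances
  truncation is effectively never active.
- Replicates derive their seeds from the master seed through a fixed
  integer recurrence, so results are independent of execution order and
  bit-reproducible per (config, seed).
- Summary rows log N and biomass of the start-of-year state (the same
  state that sets density dependence), which makes the logs verifiable by
  chaining; cross-sections (length-at-age, maturity ogives) are surveyed
  after growth and maturation. Empty age classes are reported missing,
  not zero, to avoid biasing growth curves. End-of-run reporting averages
  the final 200 years; replicate aggregation is the mean of replicate
  means with between-replicate SD.

## What the generator emulates — and what it does not

The synthetic-data generator (`make_population()`) produces seedable
populations with a truncated-geometric age structure, von Bertalanffy
mean lengths with 8% multiplicative noise, weights on the length–weight
curve and traits at the inheritance-equilibrium spread: enough structure
for every module contract to be exercised in milliseconds. It does not
emulate survey data, cohort autocorrelation, or the joint trait–size
distribution of an evolved population — which is why the engine tests
that need realistic structure first run a spin-up.

Passing tests on this generator demonstrate internal consistency
(budgets, contracts, directions of selection) at desk scale; they do not
validate the model against stock-assessment data, and the absolute
numbers (population size, biomass) have no field meaning.

## Known limitations

- No seasons, geography, migration or explicit prey fields; food supply
  is temperature-independent by design.
- Intake capacity does not rise with temperature while metabolic costs
  do (Q10 = 2); at the warmest scenario (+8.4 °C) energy budgets tighten
  and the desk-scale SSP3 population equilibrates *smaller* than
  baseline, although the within-scenario effects of fishing (fewer,
  earlier-maturing fish at higher `F_max`) hold there too. A
  temperature-dependent intake ceiling would be the natural extension.
- Sex is implicit; there are no maternal effects and no explicit loci.
- The desk-scale unfished/fished contrast is compressed (see above).
- Gear exposure is redrawn annually, so the 70/30 split is a fleet-level
  exposure probability, not a lifetime assignment.
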