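# codibm

An individual-based, mechanistic eco-evolutionary simulator of the
Northeast Arctic (NEA) cod stock (*Gadus morhua*) under concurrent
size-selective fishing and climate warming. The package is for
fisheries-evolution modellers who want to study how two heritable
life-history traits — **appetite** (target annual energy intake) and the
**intercept of the probabilistic maturation reaction norm (PMRN)** —
respond when warming and fishing act together on a cold-water stock, and
what that adaptation does to growth curves, maturation schedules,
population size and mortality.

## The model

Fish live in annual time steps from age 1 to at most 20 years. Each year,
every individual:

1. **Forages** toward its appetite-set target intake. Food availability is
   density dependent, `a(B) = 1 / (1 + B / B_half)`, so a larger standing
   biomass forces more foraging effort per joule.
2. **Pays metabolic costs** `c_SMR · W^0.7 · Q10^((T−4)/10)` plus an
   activity cost proportional to effort. An **oxygen budget** converts
   metabolised energy to oxygen demand (13.6 J per mg O₂) and caps effort
   so demand never exceeds the maximum uptake
   `c_MMR · W^0.7 · g(T)`, where `g` is a dome peaking near 13 °C — so
   aerobic scope *widens* as the Barents Sea warms from 4 °C.
3. **Allocates** net energy: immature fish grow somatically; mature fish
   put a fraction `min(r0 + k_r · years-post-maturation, r_cap)` into
   gonads. Weight follows `W = k_cond · L³`; length is structural and
   never shrinks.
4. **Matures** (irreversibly) by a Bernoulli trial on the PMRN: the
   probability is logistic in length around `Lp50 = intercept + slope · age`.
5. **Survives** six additive instantaneous mortality components: fixed,
   predation (declining with size), foraging (rising with effort),
   reproduction (rising with the gonadosomatic index), respiration
   (convex in oxygen usage) and fishing
   `F = F_max · U(L)`, with gillnet selectivity
   `U_G(L) = exp(−(L − L_max)² / (2σ²))` and trawl selectivity equal to
   `U_G` below `L_max` and 1 above it (`L_max` = 110 cm,
   `σ = 0.28 · L_max`); each year 70% of individuals meet the trawl fleet
   and 30% the gillnets.
6. **Reproduces**: total eggs follow from gonad energy; age-1 recruits
   follow Beverton–Holt recruitment `R = αE / (1 + E/β)`; each recruit's
   two parents are drawn weighted by gonad mass, and its genetic values
   are the midparent values plus Gaussian noise, expressed with
   environmental deviation (calibrated so the emergent midparent–offspring
   heritability is ≈ 0.2).

Temperature follows one of four scenarios: a 4 °C baseline, or warming
trajectories stabilising at 4.8 °C (SSP1), 7.0 °C (SSP2) or 12.4 °C
(SSP3) within 100–500 years, with optional interannual noise.

## Worked example

```r
library(codibm)

## spin the population up to eco-evolutionary equilibrium
sp <- spin_up(cod_params(), years = 500, seed = 1, init_n = 1000)
sp
#> <cod_spinup> 500 yr at F_max = 0.2 , 4 deg C, seed 1
#>   final N = 2447 , biomass = 23581 kg
#>   appetite trend (final 10%): +0.000202 +/- 1.22e-05 per yr
#>   pmrn trend (final 10%): +0.0154 +/- 0.00181 per yr

## a replicated warming experiment from that snapshot
run <- run_scenario(temperature_scenario("SSP1"), fishery_config(F_max = 0.2),
                    cod_params(), sp$population,
                    years = 300, replicates = 3, seed = 42)
summary(run)
#> Scenario SSP1 at F_max = 0.2 : 3 replicate(s) x 300 yr; end window 200 yr
#>   N        : 2603 +/- 3.27 individuals
#>   biomass  : 2.553e+04 +/- 132 kg
#>   appetite : 1.345 +/- 0.00552 (genetic mean)
#>   PMRN int.: 101.1 +/- 0.18 cm
#>   total M  : 0.3309 +/- 0.00202 per yr (fishing 0.0851)
#>   maturation: age 4.36 +/- 0.82 yr, length 99.2 +/- 17.7 cm (143769 events)
#>   heritability: appetite 0.20, PMRN 0.19 (646924 recruits)
```

Reading the output: under mild warming (SSP1) the population ends slightly
larger than its 4 °C starting point (2603 vs 2447 individuals) because the
widened aerobic scope lowers respiration mortality; the genetic appetite
mean rises from ~1.2 to 1.35 and the PMRN intercept climbs to ~101 cm —
selection toward later maturation at larger size — while fishing
contributes 0.085/yr of the 0.33/yr total mortality. The emergent
heritability of both traits sits at the calibrated ≈ 0.2.

`growth_curve()`, `maturation_summary()`, `maturity_ogive()`,
`relative_population()`, `end_state()`, `mortality_decomposition()` and
`heritability_report()` compute the standard output surfaces;
`plot(run)` draws the annual series. `inst/cli/codibm.R` exposes
`spinup`, `run`, `grid`, `summarize` and `make-pop` subcommands for shell
use.

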