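---
title: "Simulating tobacco control policies with smokesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tobacco control policies with smokesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`smokesim` is a deterministic, discrete annual-time, multi-state cohort
simulator of cigarette smoking at national scale. Its purpose is
counterfactual analysis: how different would smoking prevalence and
smoking-attributable deaths (SADs) have been under a different tobacco
control policy schedule?

The state of the system in any year is a population count for every
combination of single year of age (0 to an open-ended 100+ bin), gender, and
smoking status: *never smoker*, *current smoker*, or *former smoker by years
since quitting* (yearly bins 1--15 plus an absorbing 16+ bin). Four
components advance this state one year at a time:

1. **Demography.** Each cohort survives all-cause mortality and ages one
   year; births, computed from age-specific fertility applied to
   start-of-year female counts, enter the never-smoker pool at age 0.
2. **Smoking behaviour.** A first-order Markov process: never smokers
   initiate (through age 29, where prevalence curves level off), current
   smokers quit into former bin 1 (cessation is tracked above age 29),
   and former smokers either relapse with a probability that declines with
   duration or advance one duration bin. Initiation is not observed
   directly: it is measured as the rise of the prevalence curve across one
   cohort-year, `max(0, prev(a) - prev_lastyear(a - 1))`, converted to a
   probability among never smokers. Negative rises are clamped to zero so
   no state count can go negative.
3. **Mortality attribution.** All-cause mortality `m` of each age-gender
   cell is partitioned across smoking states using relative risks
   (never = 1): the never-smoker rate solves
   `m_never = m / (p_never + rr_cur p_cur + sum_k rr_former(k) p_former(k))`,
   so the share-weighted rates recombine exactly to `m`. SADs are the
   excess deaths among current and former smokers relative to `m_never`,
   counted at ages 30 and above (younger smokers carry no excess risk in
   the default schedule, so policy effects on youth show up as deaths
   averted only decades later).
4. **Policies.** A schedule gives per-year levels for seven domains:
   price, smoke-free air laws, mass media campaigns, marketing bans,
   health warnings, cessation treatment, and youth access restrictions.

Because each part is deterministic, identical inputs give bitwise-identical
outputs; a seeded stochastic microsimulation (`simulate_smoking_microcohort`,
`simulate_population_micro`) is included purely as an independent
verification route whose mean is the compartment model.

## Policy effects

Effect sizes are fractional reductions relative to *no policy at all*. The
conversion from schedule levels to simulated effects follows five rules:

* **Three channels.** An effect acts on prevalence once, in the year the
  policy (or price change) appears -- that fraction of current smokers moves
  to former bin 1, quitting being the mechanism -- and on the flows every
  year it is sustained: initiation is multiplied by `(1 - effect)` and
  cessation by `(1 + effect)`. Domains with a published channel split
  (marketing, warnings, cessation treatment, youth access) use it; the
  others apply the same size to all three channels.
* **Price** uses constant-elasticity compounding of the per-10%-increase
  reductions (6% at ages 15--17, 4% at 18--24, 2% at 25--34, 1% at 35+):
  `reduction = 1 - ratio^(log(1 - x)/log(1.1))`. A 10% rise returns `x`
  exactly; large rises compound without reaching 100%; a price fall yields
  a negative reduction. Price is a *level* effect recomputed yearly from
  the real-price index, so only year-over-year price changes move the
  stock. Ages below 15 take the 15--17 band; for under-18s the price and
  youth-access effects act on prevalence and initiation only.
* **Incrementality.** Every domain's effect is measured against its
  base-year level through the product rule,
  `e_inc = 1 - (1 - e_now)/(1 - e_base)`: an unchanged domain contributes
  exactly zero (this is what makes a frozen schedule reproduce the
  no-policy trajectory), and strengthening an existing policy is worth
  less than introducing it outright.
* **Combination.** Domains combine multiplicatively,
  `total = 1 - prod(1 - e_d)` -- order-independent and bounded below 100%.
  Cessation increases combine as products of `(1 + c_d)`.
* **Enforcement and synergy.** Enforcement scores in `[0, 1]` scale the
  smoke-free and marketing effects linearly between 50% and 100% of full
  size. Media campaign effects double when any other domain is away from
  its base-year level that year ("other policies active" is defined this
  way because the schedule is the only machine-readable notion of policy
  activity).

Lower/upper effect-size bounds are propagated through full runs as
per-domain multipliers: price 0.75/1.25; smoke-free, marketing, warnings,
media 0.5/1.5; cessation treatment 0.5/2.0 (delivery could improve); youth
access 0/1.5 (many studies find no effect). The "upper" scenario therefore
has the *lowest* prevalence; bound runs nest the central run every year.

## Key parameters

| parameter | default | units / rationale |
|---|---|---|
| initiation cutoff | age 29 | prevalence curves level off by the late 20s |
| cessation rate | 0.05 / yr above 29 | first-quit rate before relapse |
| relapse | 0.12 ... 0.005 by years quit | monotone packaged default |
| rr current | 2.1 at ages 30+ | cohort-study magnitude; 1.6 variant available |
| rr former | linear 2.1 to 1 by 16+ yrs | risk recedes after quitting |
| sex ratio at birth | 0.512 male | demographic constant |
| SAD minimum age | 30 | excess risk onset |

All of these are arguments or bundle fields, not hard-coded constants.

## The synthetic Brazil-like bundle

The published inputs behind the historical application (census demography,
the 1989 household survey, quit-duration distributions, cohort-study
relative risks) are not available as machine-readable files, so
`make_brazil_like_fixture()` builds a synthetic stand-in that preserves the
features the model's logic depends on:

* **Adult prevalence** by age group and gender equals the published 1989
  survey values exactly (male 34.1/48.4/45.5/33.5%, female
  24.2/31.4/23.7/18.4% for 18--24/25--44/45--64/65+), flat within groups
  because nothing finer is printed. The adult age structure is *derived*,
  not assumed: with the 65+ share fixed at 8% (realistic for a young
  late-1980s population), the remaining three group shares solve the linear
  system that makes the male and female 18+ aggregates equal the printed
  43.3% and 27.0% exactly.
* **Youth prevalence** ramps linearly from 0 at age 12 to the 18--24 level
  at 18, giving smooth positive derived initiation rates.
* **Former smokers** follow a rising age gradient, distributed over quit
  bins with geometrically declining weights (recent quitters most
  numerous).
* **The policy schedule 1989--2010** encodes the documented milestones:
  real prices interpolating 1.0 to 2.0 by 1998 and 2.3 by 2010; weak
  warnings 1996, graphic warnings 2001; advertising restrictions escalating
  from a weak 1989 baseline to a comprehensive ban by 2005; education and
  media programmes from 1996; smoke-free strengthening in 1996, 2000, and
  2007; cessation-treatment access from 1996; weak youth-access enforcement
  from 1997.
* **Mortality and fertility** are smooth parametric placeholders (infant
  component plus Gompertz senescence; Gaussian fertility hump with total
  fertility 2.9). They are deliberately *not* calibrated to any census.

What passing tests on this bundle show is that the machinery is correct:
accounting identities hold, policies act through the stated channels,
bounds nest, the counterfactual is exact. What they do not show is
predictive accuracy for any real country: with placeholder demography and
relative-risk schedules, absolute death counts and the precise split
between secular trend and policy effect will differ from any published
application, and headline outputs of the bundle should be read as
"Brazil-like", not "Brazil".

## Numerical choices

* **Order of operations within a year** (fixed and tested): policy effects,
  then behavioural transitions, then mortality, then aging and births.
  Relapse is applied before bin advancement, and this year's quitters
  enter bin 1 *after* advancement, so nobody skips a duration bin.
* Rates are annual probabilities, not hazards; no sub-annual time step.
* The prevalence channel's year-over-year increment can be negative (a real
  price fall); the flow then returns recent quitters (bin 1) to smoking,
  capped at the bin's occupancy.
* Adjusted cessation rates are clamped to `[0, 1]`; chained float
  arithmetic may leave counts negative at the `1e-16` level, which the
  state constructor zeroes (and anything beyond `1e-9` relative is an
  error, since it indicates invalid rates rather than roundoff).
* Mortality partition tolerates empty cells by assigning the overall rate
  to every status (the attribution is vacuous there).
* The FCTC tax step ("60% to 75% of retail price") is converted to a price
  multiplier of `0.40/0.25 = 1.6` under full pass-through at constant
  pre-tax price -- a modelling decision, documented rather than claimed.

## Problem sizes

The test-suite runs use the full 101 x 2 x 18 state space. Scenario
batteries in tests run to 2050 (62 simulated years, 25 scenario runs in the
bound battery, about 20 s in total); microsimulation oracles use cohorts of
100,000 with fixed seeds and a 3-standard-error acceptance band; the
stochastic demography check uses 200 replicates of a 10,000-person toy
population. These sizes were chosen so every behavioural contrast the model
claims (monotonicity, nesting, identities) is exercised at full state-space
resolution.

## Limitations

* No migration, no sub-national geography, no income or affordability
  feedback on price elasticities, no social-norm feedback between smokers.
* No second-hand-smoke or maternal-smoking mortality: attributable deaths
  are active-smoking excess only.
* No smoking intensity (cigarettes/day) or other tobacco products.
* Mortality and fertility are static over the projection (no demographic
  trend), which mainly affects long-horizon death counts.
* The packaged relapse and relative-risk schedules are synthetic defaults;
  applications to a real country should replace them (every bundle field is
  writable) and validate against surveys, as the historical applications of
  this model class do.
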