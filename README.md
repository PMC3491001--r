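# smokesim

Deterministic simulation of tobacco control policies, smoking prevalence,
and smoking-attributable mortality.

## What it is for

Tobacco control rarely arrives as one policy: taxes, smoke-free air laws,
marketing bans, warning labels, media campaigns, cessation treatment, and
youth access restrictions are layered over decades, while smoking also
declines for reasons of its own. `smokesim` is for epidemiologists and
policy analysts who want to separate those strands: it projects a national
population and its smoking behaviour forward year by year, runs the same
world again with policies frozen at their base-year levels (the
counterfactual), and attributes the difference — in prevalence and in
smoking-attributable deaths (SADs) — to the policy schedule, overall and
policy by policy.

## The model

The state is a count for every (age 0–100+, gender, smoking status) cell,
with former smokers tracked by years since quitting (bins 1–15, 16+).
Annually:

* **Demography** — cohorts survive mortality *q(a,g)* and age; births enter
  at age 0.
* **Smoking** — a first-order Markov chain: initiation through age 29
  (measured as the prevalence-curve rise across a cohort-year), cessation
  above 29, duration-dependent relapse.
* **Attribution** — all-cause mortality *m* splits by status via relative
  risks: *m_never* = *m* / (*p_nev* + RR_cur *p_cur* + Σ_k RR_for(k)
  *p_for(k)*), and SAD = Σ smokers × (status rate − *m_never*) at ages 30+.
* **Policies** — per-domain effect sizes act on prevalence when
  implemented and on initiation/cessation while sustained, combined
  multiplicatively: *E* = 1 − Π(1 − *e_d*), each *e_d* incremental over its
  base-year level, enforcement-scaled, with media synergy and per-domain
  lower/upper bounds. Price uses constant-elasticity compounding of
  age-banded per-10%-increase reductions.

Everything is deterministic; a seeded binomial microsimulation of the same
chains ships as an independent cross-check.

## Worked example

```r
library(smokesim)

bundle <- make_brazil_like_fixture()        # complete synthetic input set
cf  <- run_scenario(bundle, freeze_schedule(bundle$schedule), 2010,
                    label = "counterfactual", policies = FALSE)
pol <- run_scenario(bundle, horizon = 2010, label = "all_policies")
render_comparison_table(list(counterfactual = cf, all_policies = pol),
                        years = c(1989, 2000, 2010))
#>         quantity       scenario 1989   2000    2010
#> 1 prevalence_pct counterfactual 35.2   32.5    30.6
#> 2 prevalence_pct   all_policies 35.2   23.5    17.3
#> 3 deaths_averted   all_policies  0.0 4479.0 29154.0
```

Both worlds start at the same adult prevalence (35.2%). Without the
post-1989 policies, prevalence drifts down slowly through background
cessation (30.6% by 2010); with the schedule — prices reaching 2.3× their
real 1989 level, graphic warnings, an advertising ban, smoke-free laws,
media and cessation programmes — it falls to 17.3%, a
`relative_reduction(0.173, 0.306)` ≈ 43% relative decline, and 29,154
attributable deaths are averted in 2010 alone in this synthetic population.
`run_standard_scenarios()` adds the seven single-policy runs and
lower/upper effect-size bounds; `decompose_contributions()` turns the
single-policy reductions into shares; `build_fctc_schedule()` constructs a
maximal-policy future scenario.

A command-line front end with `simulate`, `counterfactual`, `decompose`,
`fctc`, `bounds`, and `make-fixtures` subcommands is installed at
`system.file("scripts/smokesim.R", package = "smokesim")`.

## Scope notes

The bundled inputs are synthetic ("Brazil-like"): published 1989 adult
prevalences and policy milestones are reproduced exactly, but demography,
relapse, and relative-risk schedules are parametric placeholders, so
absolute outputs characterise the model, not any real country. See the
methods vignette (`vignettes/policy-simulation.Rmd`) for the model's
assumptions, parameter defaults, numerical choices, and limitations.
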