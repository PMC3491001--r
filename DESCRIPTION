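Package: smokesim
Title: Deterministic Simulation of Tobacco Control Policies, Smoking
    Prevalence, and Smoking-Attributable Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A discrete annual-time, multi-state cohort simulator of cigarette
    smoking at national scale.  The population is projected by single year of
    age and gender through births and deaths, and smoking behaviour through a
    first-order Markov process of initiation, cessation, and relapse, with
    former smokers tracked by years since quitting.  Smoking-attributable
    deaths are computed by partitioning all-cause mortality across smoking
    states with relative risks and attributing the excess among current and
    former smokers.  A policy engine converts schedules for seven tobacco
    control domains (price, smoke-free air, mass media, marketing bans,
    health warnings, cessation treatment, youth access) into multiplicative
    effects on prevalence, initiation, and cessation, with enforcement
    scaling, media synergy, and lower/upper effect-size bounds.  Scenario
    tools run counterfactual, single-policy, and FCTC-style maximal-policy
    scenarios and compute deaths averted and per-policy contribution
    decompositions.  Includes a self-consistent Brazil-like synthetic input
    bundle and a stochastic microsimulation oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
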