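# Policy engine: effect sizes for the seven tobacco-control domains, price
# elasticity compounding, multiplicative effect combination, enforcement
# scaling, media synergy, and lower/upper effect-size bounds.
#
# Effect sizes follow the standard published schedule for a middle-income
# setting: each value is the fractional reduction relative to no policy at
# all, applied to prevalence in the implementation year and carried on
# initiation (as a reduction) and cessation (as an increase) while the
# policy is sustained, unless a domain specifies its own channel split.

#' The seven tobacco-control policy domains
#'
#' Domain names used throughout schedules, effect sets, and scenario labels.
#' @export
POLICY_DOMAINS <- c("price", "smokefree", "media", "marketing", "warnings",
                    "cessation_treatment", "youth_access")

# per-10%-price-increase prevalence reductions by age band; ages < 15 take
# the youngest band
price_band <- function(age) {
  ifelse(age <= 17, 0.06,
         ifelse(age <= 24, 0.04,
                ifelse(age <= 34, 0.02, 0.01)))
}

# additive components of a smoke-free air law
SMOKEFREE_EFFECTS <- c(worksite = 0.090, restaurant = 0.030,
                       bar = 0.015, other = 0.010)

# mutually exclusive campaign intensities (doubled when other policies are
# active in the same year)
MEDIA_EFFECTS <- c(none = 0, low = 0.005, moderate = 0.018, high = 0.0325)

# mutually exclusive marketing-restriction levels, with channel splits
MARKETING_EFFECTS <- list(
  none          = c(prevalence = 0,    initiation = 0,    cessation = 0),
  weak          = c(prevalence = 0.02, initiation = 0.02, cessation = 0),
  total         = c(prevalence = 0.06, initiation = 0.08, cessation = 0.04),
  comprehensive = c(prevalence = 0.10, initiation = 0.12, cessation = 0.06))

# mutually exclusive warning-label levels
WARNING_EFFECTS <- list(
  none   = c(prevalence = 0,    initiation = 0,    cessation = 0),
  weak   = c(prevalence = 0.01, initiation = 0.01, cessation = 0.02),
  strong = c(prevalence = 0.04, initiation = 0.04, cessation = 0.10))

# complete cessation-treatment availability (level scales linearly)
CESSATION_TX_EFFECT <- c(prevalence = 0.0675, cessation = 0.55)

# mutually exclusive youth-access levels: under-16 / 16-17 reductions,
# prevalence and initiation only
YOUTH_EFFECTS <- list(
  none     = c(u16 = 0,    a1617 = 0),
  low      = c(u16 = 0.03, a1617 = 0.02),
  moderate = c(u16 = 0.15, a1617 = 0.10),
  strong   = c(u16 = 0.30, a1617 = 0.20))

#' Lower/upper effect-size multipliers per policy domain
#'
#' Price effects carry the tightest bounds (+/-25%, reflecting the
#' consistency of price studies); smoke-free air, marketing, warnings, and
#' media carry +/-50%; cessation treatment -50%/+100% (treatment delivery
#' could improve); youth access from no effect to +50% (many studies find
#' none).
#'
#' @return data.frame with columns `domain`, `lower`, `upper`.
#' @export
effect_bounds <- function() {
  data.frame(
    domain = POLICY_DOMAINS,
    lower = c(0.75, 0.5, 0.5, 0.5, 0.5, 0.5, 0.0),
    upper = c(1.25, 1.5, 1.5, 1.5, 1.5, 2.0, 1.5))
}

bound_multiplier <- function(domain, bound = c("central", "lower", "upper")) {
  bound <- match.arg(bound)
  if (bound == "central") return(1)
  eb <- effect_bounds()
  eb[[bound]][match(domain, eb$domain)]
}

# Enforcement scales an effect linearly from 50% (score 0) to 100% (score 1).
enforcement_scale <- function(score) {
  if (any(score < 0 | score > 1))
    stop("enforcement score must be in [0, 1]", call. = FALSE)
  0.5 + 0.5 * score
}

#' Prevalence reduction from a real-price change
#'
#' Constant-elasticity compounding of the per-10%-increase effect sizes:
#' `reduction(a) = 1 - ratio^(log(1 - x_a) / log(1.1))`, where `x_a` is the
#' age band's reduction per 10% price increase (6% at 15-17, 4% at 18-24,
#' 2% at 25-34, 1% at 35+).  A ratio of exactly 1.1 returns `x_a`; large
#' increases compound without ever reaching 100%; a ratio below 1 yields a
#' negative reduction (a prevalence increase).
#'
#' @param price_ratio current real price divided by base-year real price
#'   (positive scalar).
#' @param age vector of ages.
#' @param per10 optional override of the per-10% effect size(s).
#' @return vector of fractional reductions, one per age.
#' @examples
#' price_effect(1.1, 16)   # 0.06 exactly
#' price_effect(2.3, 40)   # ~0.084: a 130% price rise at the 1% band
#' @export
price_effect <- function(price_ratio, age, per10 = NULL) {
  if (any(price_ratio <= 0))
    stop("price ratio must be positive", call. = FALSE)
  x <- if (is.null(per10)) price_band(age) else rep(per10, length.out = length(age))
  1 - price_ratio^(log(1 - x) / log(1.1))
}

#' Combine fractional effects multiplicatively
#'
#' Each additional effect is discounted by the effects already in place:
#' `combined = 1 - prod(1 - e_i)`.  The result is order-independent and
#' strictly below 1 (negative effects, e.g. from a price decrease, are
#' allowed and push the total down).
#'
#' @param effects numeric vector of fractional reductions, each `< 1`.
#' @return the combined fractional reduction; 0 for an empty set.
#' @examples
#' combined_effect(c(0.10, 0.05))  # 0.145
#' @export
combined_effect <- function(effects) {
  effects <- as.numeric(effects)
  if (length(effects) == 0L) return(0)
  if (anyNA(effects) || any(effects >= 1))
    stop("every effect must be < 1", call. = FALSE)
  1 - prod(1 - effects)
}

# Raw (non-incremental) channel effects of one domain at the levels given in
# a schedule row: list(prevalence, initiation, cessation) vectors over ages.
# `cessation` is the fractional *increase* in the cessation rate.
domain_channel_effects <- function(row, domain, ages, bound_mult = 1,
                                   synergy = FALSE) {
  zero <- numeric(length(ages))
  prev <- init <- cess <- zero
  if (domain == "price") {
    e <- price_effect(row$price_index, ages,
                      per10 = price_band(ages) * bound_mult)
    prev <- init <- cess <- e
    cess[ages < 18] <- 0            # youth price response is uptake-side only
  } else if (domain == "smokefree") {
    lvl <- row$sf_worksite * SMOKEFREE_EFFECTS[["worksite"]] +
      row$sf_restaurant * SMOKEFREE_EFFECTS[["restaurant"]] +
      row$sf_bar * SMOKEFREE_EFFECTS[["bar"]] +
      row$sf_other * SMOKEFREE_EFFECTS[["other"]]
    e <- lvl * enforcement_scale(row$sf_enforcement) * bound_mult
    prev <- init <- cess <- rep(e, length(ages))
  } else if (domain == "media") {
    if (!row$media %in% names(MEDIA_EFFECTS))
      stop("unknown media level '", row$media, "'", call. = FALSE)
    e <- MEDIA_EFFECTS[[row$media]] * (if (synergy) 2 else 1) * bound_mult
    prev <- init <- cess <- rep(e, length(ages))
  } else if (domain == "marketing") {
    if (!row$marketing %in% names(MARKETING_EFFECTS))
      stop("unknown marketing level '", row$marketing, "'", call. = FALSE)
    v <- MARKETING_EFFECTS[[row$marketing]] *
      enforcement_scale(row$marketing_enforcement) * bound_mult
    prev <- rep(v[["prevalence"]], length(ages))
    init <- rep(v[["initiation"]], length(ages))
    cess <- rep(v[["cessation"]], length(ages))
  } else if (domain == "warnings") {
    if (!row$warnings %in% names(WARNING_EFFECTS))
      stop("unknown warnings level '", row$warnings, "'", call. = FALSE)
    v <- WARNING_EFFECTS[[row$warnings]] * bound_mult
    prev <- rep(v[["prevalence"]], length(ages))
    init <- rep(v[["initiation"]], length(ages))
    cess <- rep(v[["cessation"]], length(ages))
  } else if (domain == "cessation_treatment") {
    lvl <- row$cessation_treatment
    if (lvl < 0 || lvl > 1)
      stop("cessation_treatment level must be in [0, 1]", call. = FALSE)
    prev <- rep(CESSATION_TX_EFFECT[["prevalence"]] * lvl * bound_mult,
                length(ages))
    cess <- rep(CESSATION_TX_EFFECT[["cessation"]] * lvl * bound_mult,
                length(ages))
  } else if (domain == "youth_access") {
    if (!row$youth_access %in% names(YOUTH_EFFECTS))
      stop("unknown youth_access level '", row$youth_access, "'", call. = FALSE)
    v <- YOUTH_EFFECTS[[row$youth_access]] * bound_mult
    e <- ifelse(ages < 16, v[["u16"]], ifelse(ages <= 17, v[["a1617"]], 0))
    prev <- init <- e
  } else stop("unknown policy domain '", domain, "'", call. = FALSE)
  list(prevalence = prev, initiation = init, cessation = cess)
}

# Is any non-media domain away from its base-year level in this row?
other_policies_active <- function(row, base) {
  abs(row$price_index - base$price_index) > 1e-12 ||
    row$sf_worksite != base$sf_worksite ||
    row$sf_restaurant != base$sf_restaurant ||
    row$sf_bar != base$sf_bar ||
    row$sf_other != base$sf_other ||
    row$marketing != base$marketing ||
    row$warnings != base$warnings ||
    abs(row$cessation_treatment - base$cessation_treatment) > 1e-12 ||
    row$youth_access != base$youth_access
}

#' Policy effects for one simulated year
#'
#' Converts the schedule's levels for the given year into per-age effects on
#' the three channels, *incremental over the base-year levels*: a domain that
#' never moves contributes nothing (the counterfactual identity), and the
#' incremental effect of strengthening an existing policy is discounted by
#' the part already in place.  Per domain: raw effect at current level (with
#' enforcement scaling, media synergy doubling, and the bound multiplier),
#' then `e_inc = 1 - (1 - e_now) / (1 - e_base)`; domains combine through the
#' product rule.  Cessation increases combine as products of `(1 + c)`.
#'
#' @param schedule a [policy_schedule()].
#' @param year simulated year (must be covered by the schedule).
#' @param bound `"central"`, `"lower"`, or `"upper"` effect-size variant.
#' @param ages age grid the effects are evaluated on.
#' @return an object of class `effect_set`: list of per-age vectors
#'   `prevalence`, `initiation` (fractional reductions) and `cessation`
#'   (fractional increase), plus `ages`.
#' @export
schedule_to_effects <- function(schedule, year,
                                bound = c("central", "lower", "upper"),
                                ages = DEFAULT_AGES) {
  bound <- match.arg(bound)
  sc <- as.data.frame(schedule)
  base_year <- attr(schedule, "base_year")
  if (!year %in% sc$year)
    stop("year ", year, " is not covered by the schedule", call. = FALSE)
  row <- sc[sc$year == year, , drop = FALSE]
  base <- sc[sc$year == base_year, , drop = FALSE]
  synergy <- other_policies_active(row, base)
  keep_prev <- keep_init <- rep(1, length(ages))
  cess_mult <- rep(1, length(ages))
  for (d in POLICY_DOMAINS) {
    bm <- bound_multiplier(d, bound)
    now <- domain_channel_effects(row, d, ages, bm, synergy = synergy)
    ref <- domain_channel_effects(base, d, ages, bm, synergy = FALSE)
    keep_prev <- keep_prev * (1 - now$prevalence) / (1 - ref$prevalence)
    keep_init <- keep_init * (1 - now$initiation) / (1 - ref$initiation)
    cess_mult <- cess_mult * (1 + now$cessation) / (1 + ref$cessation)
  }
  structure(list(prevalence = 1 - keep_prev,
                 initiation = 1 - keep_init,
                 cessation = cess_mult - 1,
                 ages = ages),
            class = "effect_set", year = year, bound = bound)
}

zero_effects <- function(ages = DEFAULT_AGES) {
  structure(list(prevalence = numeric(length(ages)),
                 initiation = numeric(length(ages)),
                 cessation = numeric(length(ages)),
                 ages = ages),
            class = "effect_set", year = NA_integer_, bound = "central")
}

#' Apply policy effects to a smoking state and its transition rates
#'
#' The prevalence channel acts once, when the effect first appears: the
#' year-over-year *increment* of the cumulative prevalence effect moves that
#' fraction of current smokers into former bin 1 (quitting is the mechanism).
#' The initiation and cessation channels act on the flows every sustained
#' year: initiation is multiplied by `(1 - effect)`, cessation by
#' `(1 + effect)` (clamped to `[0, 1]`).
#'
#' @param state a [smoking_state()].
#' @param rates the *background* [transition_rates()] (policy-free).
#' @param effects this year's [schedule_to_effects()] output.
#' @param prev_effects last year's effect set, or `NULL` if every effect is
#'   newly implemented (the increment is then the full effect).
#' @return list with elements `state` and `rates`, adjusted.
#' @export
apply_effects <- function(state, rates, effects, prev_effects = NULL) {
  stopifnot(inherits(state, "smoking_state"),
            inherits(rates, "transition_rates"))
  before <- if (is.null(prev_effects)) numeric(length(effects$ages))
            else prev_effects$prevalence
  delta <- 1 - (1 - effects$prevalence) / (1 - before)
  move_out <- sweep(state$current, 1L, pmax(delta, 0), `*`)
  # a weakening effect (e.g. falling real price) pulls recent quitters back
  move_back <- pmin(state$former[, , 1L],
                    sweep(state$current, 1L, pmax(-delta, 0), `*`))
  former <- state$former
  former[, , 1L] <- former[, , 1L] + move_out - move_back
  new_state <- smoking_state(state$never,
                             state$current - move_out + move_back, former)
  clamp01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
  initiation <- clamp01(sweep(rates$initiation, 1L,
                              1 - effects$initiation, `*`))
  cessation <- clamp01(sweep(rates$cessation, 1L,
                             1 + effects$cessation, `*`))
  new_rates <- transition_rates(initiation, cessation, rates$relapse,
                                init_age_max = rates$init_age_max)
  list(state = new_state, rates = new_rates)
}
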