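# Synthetic input bundles.  make_brazil_like_fixture() builds a complete,
# self-consistent Brazil-like world seeded with the published 1989 adult
# prevalences by age group and the 1989-2010 policy milestones; demographic
# curves are smooth parametric placeholders, so demographic outputs are not
# claims about Brazil.  make_toy_fixture() builds a tiny closed-form world
# for oracle tests.

# 1989 household-survey smoking prevalence by adult age group (percent/100).
BASE_PREVALENCE_1989 <- list(
  groups = c("18-24", "25-44", "45-64", "65+"),
  lo = c(18, 25, 45, 65), hi = c(24, 44, 64, Inf),
  male = c(0.341, 0.484, 0.455, 0.335),
  female = c(0.242, 0.314, 0.237, 0.184),
  adult_male = 0.433, adult_female = 0.270)

# Baseline former-smoker share by the same groups (synthetic, loosely
# Netherlands-like in level and age gradient).
BASE_FORMER_1989 <- list(male = c(0.05, 0.12, 0.20, 0.25),
                         female = c(0.03, 0.08, 0.12, 0.15))

# Default relapse probabilities by years-quit bin (1..15, 16+): a packaged
# synthetic schedule, monotone non-increasing in duration.
DEFAULT_RELAPSE <- c(0.12, 0.09, 0.07, 0.05, 0.04, 0.03, 0.025, 0.02, 0.02,
                     0.015, 0.015, 0.01, 0.01, 0.01, 0.01, 0.005)

# Adult age-group population shares chosen so that the group prevalences
# aggregate exactly to the printed 18+ rates for BOTH genders: with the 65+
# share fixed (realistic for a young late-1980s population), the remaining
# three shares solve a linear system.
adult_group_shares <- function(share_65plus = 0.08) {
  p <- BASE_PREVALENCE_1989
  A <- rbind(c(1, 1, 1), p$male[1:3] * 100, p$female[1:3] * 100)
  b <- c(1 - share_65plus,
         p$adult_male * 100 - p$male[4] * 100 * share_65plus,
         p$adult_female * 100 - p$female[4] * 100 * share_65plus)
  s <- solve(A, b)
  if (any(s <= 0)) stop("infeasible population shares", call. = FALSE)
  c(s, share_65plus)
}

group_of_age <- function(age) {
  p <- BASE_PREVALENCE_1989
  idx <- rep(NA_integer_, length(age))
  for (g in seq_along(p$groups))
    idx[age >= p$lo[g] & age <= p$hi[g]] <- g
  idx
}

# Single-age prevalence curve for one gender: zero through age 12, a linear
# ramp to the youngest adult group's level over 13-17, then flat within each
# adult group (no finer published breakdown).
baseline_prevalence_curve <- function(gender, ages = DEFAULT_AGES) {
  p <- BASE_PREVALENCE_1989[[gender]]
  out <- numeric(length(ages))
  ramp <- ages >= 13 & ages <= 17
  out[ramp] <- p[1] * (ages[ramp] - 12) / 6
  adult <- !is.na(group_of_age(ages))
  out[adult] <- p[group_of_age(ages[adult])]
  out
}

baseline_former_curve <- function(gender, ages = DEFAULT_AGES) {
  f <- BASE_FORMER_1989[[gender]]
  out <- numeric(length(ages))
  adult <- !is.na(group_of_age(ages))
  out[adult] <- f[group_of_age(ages[adult])]
  out
}

# Brazil-like policy milestones, 1989-2010: prices doubled by 1998 and 2.3x
# by 2010; weak warnings 1996, graphic 2001; advertising restrictions
# escalating to broad coverage by 2005; education/media from 1996; smoke-free
# strengthening 1996, 2000 and 2007; cessation-treatment access from 1996.
#' Brazil-like policy schedule, 1989-2010
#'
#' @return a [policy_schedule()] with base year 1989.
#' @export
brazil_policy_schedule <- function() {
  years <- 1989:2010
  price <- c(seq(1, 2, length.out = 10),              # 1989..1998
             seq(2, 2.3, length.out = 13)[-1])        # 1999..2010
  df <- data.frame(
    year = years, price_index = price,
    sf_worksite = 0, sf_restaurant = 0, sf_bar = 0, sf_other = 0,
    sf_enforcement = 0.5,
    media = "none", marketing = "weak", marketing_enforcement = 0.5,
    warnings = "none", cessation_treatment = 0, youth_access = "none",
    stringsAsFactors = FALSE)
  set_from <- function(df, year, col, value) {
    df[[col]][df$year >= year] <- value
    df
  }
  df <- set_from(df, 1996, "warnings", "weak")
  df <- set_from(df, 2001, "warnings", "strong")
  df <- set_from(df, 1996, "media", "low")
  df <- set_from(df, 2002, "media", "moderate")
  df <- set_from(df, 1996, "sf_restaurant", 1)
  df <- set_from(df, 1996, "sf_other", 1)
  df <- set_from(df, 2000, "sf_worksite", 1)
  df <- set_from(df, 2007, "sf_bar", 1)
  df <- set_from(df, 2007, "sf_enforcement", 0.6)
  df <- set_from(df, 2000, "marketing", "total")
  df <- set_from(df, 2005, "marketing", "comprehensive")
  df <- set_from(df, 2005, "marketing_enforcement", 0.8)
  df <- set_from(df, 1996, "cessation_treatment", 0.25)
  df <- set_from(df, 2005, "cessation_treatment", 0.5)
  df <- set_from(df, 1997, "youth_access", "low")
  policy_schedule(df, base_year = 1989L)
}

#' Brazil-like synthetic input bundle
#'
#' A complete, internally consistent input set for the simulator, emulating
#' the shape of the real 1989 Brazilian inputs: a young population of 147
#' million whose adult age-group shares make the published group prevalences
#' aggregate exactly to the printed 18+ rates (43.3% male, 27.0% female);
#' Gompertz-like mortality with an infant component; a Gaussian fertility
#' hump (total fertility about 2.9); baseline cessation of 5% per year above
#' age 29 before relapse; initiation rates derived from the baseline
#' prevalence curve; a duration-graded relapse schedule; current-smoker
#' relative risk 2.1 at ages 30+ receding to 1 by 16+ years quit; and the
#' 1989-2010 policy milestone schedule.  The bundle is fully deterministic;
#' `seed` is recorded for companion stochastic runs.
#'
#' @param seed integer recorded in the bundle (the bundle itself involves no
#'   randomness, so regeneration with any seed is identical apart from the
#'   recorded value).
#' @param total_population baseline population size.
#' @param rr_current current-smoker relative risk at ages 30+.
#' @return an object of class `fixture_bundle`: a list with elements
#'   `base_year`, `ages`, `population`, `fertility`, `mortality`,
#'   `sex_ratio_male`, `state`, `rates`, `rr`, `schedule`, `seed`.
#' @export
make_brazil_like_fixture <- function(seed = 1L, total_population = 147e6,
                                     rr_current = 2.1) {
  ages <- DEFAULT_AGES
  n <- length(ages)
  shares <- adult_group_shares()
  # within-group single-age weights: gentle exponential decay; steeper in
  # the open-ended 65+ group
  age_weights <- numeric(n)
  for (g in seq_along(shares)) {
    lo <- BASE_PREVALENCE_1989$lo[g]
    hi <- min(BASE_PREVALENCE_1989$hi[g], max(ages))
    sel <- ages >= lo & ages <= hi
    decay <- if (g == 4L) 0.06 else 0.025
    w <- exp(-decay * (ages[sel] - lo))
    age_weights[sel] <- shares[g] * w / sum(w)
  }
  adult_total <- 0.58
  age_weights <- age_weights * adult_total
  young <- ages <= 17
  wy <- exp(-0.012 * ages[young])
  age_weights[young] <- (1 - adult_total) * wy / sum(wy)
  pop <- ag_grid(rep(total_population * age_weights / 2, 2L), ages = ages)

  # mortality: infant component + floor + Gompertz senescence, women lower
  mort_curve <- function(a, b) pmin(0.98, 0.05 * exp(-0.9 * a) + 2e-4 +
                                      b * exp(0.09 * a))
  mortality <- ag_grid(c(mort_curve(ages, 5.0e-5),
                         mort_curve(ages, 3.5e-5)), ages = ages)
  # fertility: Gaussian hump over ages 15-49, total fertility ~2.9
  fert <- numeric(n)
  fecund <- ages >= 15 & ages <= 49
  shape <- dnorm(ages[fecund], mean = 26, sd = 7)
  fert[fecund] <- 2.9 * shape / sum(shape)

  cur_m <- baseline_prevalence_curve("male", ages)
  cur_f <- baseline_prevalence_curve("female", ages)
  fmr_m <- baseline_former_curve("male", ages)
  fmr_f <- baseline_former_curve("female", ages)
  current <- pop * cbind(male = cur_m, female = cur_f)
  former_tot <- pop * cbind(male = fmr_m, female = fmr_f)
  never <- pop - current - former_tot
  # distribute former smokers over quit bins, recent quitters most numerous
  wk <- exp(-0.12 * (seq_len(N_QUIT_BINS) - 1))
  wk <- wk / sum(wk)
  former <- empty_former(ages)
  for (k in seq_len(N_QUIT_BINS)) former[, , k] <- former_tot * wk[k]
  state <- smoking_state(never, current, former)

  cess <- ag_grid(0, ages = ages)
  cess[ages > INIT_AGE_MAX, ] <- 0.05
  init <- cbind(male = derive_initiation_rates(cur_m, cur_m,
                                               never_share = 1 - cur_m - fmr_m),
                female = derive_initiation_rates(cur_f, cur_f,
                                                 never_share = 1 - cur_f - fmr_f))
  init[ages > INIT_AGE_MAX, ] <- 0
  rates <- transition_rates(ag_grid(init, ages = ages), cess, DEFAULT_RELAPSE)

  structure(list(base_year = 1989L, ages = ages, population = pop,
                 fertility = fert, mortality = mortality,
                 sex_ratio_male = 0.512, state = state, rates = rates,
                 rr = default_relative_risks(rr_current, ages),
                 schedule = brazil_policy_schedule(), seed = as.integer(seed)),
            class = "fixture_bundle")
}

#' Tiny closed-form toy bundle
#'
#' A minimal world (a handful of contiguous ages, flat rates, no policies)
#' whose behaviour is checkable by hand, for oracle tests.
#'
#' @param n_ages number of single-year ages (>= 3).
#' @param age_min first age (use 30+ to put the ages in cessation range).
#' @param pop count per cell.
#' @param mortality flat annual death probability.
#' @param fertility vector of per-age fertility (recycled), default 0.
#' @param prevalence baseline current-smoker share per cell.
#' @param cessation flat annual quit probability (only applied above age 29).
#' @param relapse relapse probabilities (scalar or length 16).
#' @param base_year first simulated year.
#' @return a `fixture_bundle` on the toy grid.
#' @export
make_toy_fixture <- function(n_ages = 3L, age_min = 0L, pop = 100,
                             mortality = 0, fertility = 0, prevalence = 0,
                             cessation = 0, relapse = 0, base_year = 2000L) {
  if (n_ages < 3L) stop("n_ages must be at least 3", call. = FALSE)
  ages <- seq(age_min, age_min + n_ages - 1L)
  popg <- ag_grid(pop, ages = ages)
  mort <- ag_grid(mortality, ages = ages)
  fert <- rep(fertility, length.out = n_ages)
  current <- popg * prevalence
  state <- smoking_state(popg - current, current, empty_former(ages))
  cess <- ag_grid(0, ages = ages)
  cess[ages > INIT_AGE_MAX, ] <- cessation
  rates <- transition_rates(ag_grid(0, ages = ages), cess, relapse,
                            ages = ages)
  sched <- policy_schedule(data.frame(
    year = base_year, price_index = 1,
    sf_worksite = 0, sf_restaurant = 0, sf_bar = 0, sf_other = 0,
    sf_enforcement = 0.5, media = "none", marketing = "none",
    marketing_enforcement = 0.5, warnings = "none",
    cessation_treatment = 0, youth_access = "none",
    stringsAsFactors = FALSE))
  rrc <- ag_grid(1, ages = ages)
  structure(list(base_year = as.integer(base_year), ages = ages,
                 population = popg, fertility = fert, mortality = mort,
                 sex_ratio_male = 0.5, state = state, rates = rates,
                 rr = relative_risks(rrc, array(1, c(n_ages, 2, N_QUIT_BINS))),
                 schedule = sched, seed = 1L),
            class = "fixture_bundle")
}
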