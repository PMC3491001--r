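# Scenario runner and comparison statistics: counterfactual, all-policy,
# single-policy, and FCTC-style maximal-policy scenarios; deaths averted,
# relative reductions, and per-policy contribution decomposition.

PREVALENCE_GROUPS <- list("18-24" = c(18, 24), "25-44" = c(25, 44),
                          "45-64" = c(45, 64), "65+" = c(65, Inf),
                          "18+" = c(18, Inf))

#' Scenario result container
#'
#' Yearly prevalence by age group and gender, yearly smoking-attributable
#' deaths, and their running cumulative total, for one scenario under one
#' effect-size bound variant.
#'
#' @param label scenario label.
#' @param bound bound variant (`"central"`, `"lower"`, `"upper"`).
#' @param prevalence data frame `year, group, gender, value` (proportions).
#' @param sads data frame `year, male, female, total`.
#' @return an object of class `scenario_result`.
#' @export
scenario_result <- function(label, bound, prevalence, sads) {
  years <- sort(unique(sads$year))
  if (!identical(as.integer(years), seq(min(years), max(years))))
    stop("scenario years must be contiguous", call. = FALSE)
  sads <- sads[order(sads$year), ]
  cum <- cumsum(sads$total)
  if (any(diff(cum) < 0))
    stop("cumulative attributable deaths must be non-decreasing",
         call. = FALSE)
  structure(list(label = label, bound = bound, years = as.integer(years),
                 prevalence = prevalence, sads = sads,
                 cum_sads = setNames(cum, years)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$label, " [", x$bound, "] ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  p <- prevalence_series(x)
  show <- x$years[x$years %% 10 == 0 | x$years == min(x$years)]
  cat("  adult (18+) prevalence:",
      paste(sprintf("%d: %.1f%%", show, 100 * p[as.character(show)]),
            collapse = ", "), "\n")
  cat("  cumulative SADs:", format(round(max(x$cum_sads)), big.mark = ","),
      "\n")
  invisible(x)
}

#' Extract a prevalence series from a scenario result
#'
#' @param result a [scenario_result()].
#' @param group one of `"18-24"`, `"25-44"`, `"45-64"`, `"65+"`, `"18+"`.
#' @param gender `"male"`, `"female"`, or `"both"`.
#' @return numeric vector of proportions named by year.
#' @export
prevalence_series <- function(result, group = "18+", gender = "both") {
  p <- result$prevalence
  sel <- p$group == group & p$gender == gender
  if (!any(sel)) stop("no such group/gender series", call. = FALSE)
  setNames(p$value[sel], p$year[sel])[as.character(result$years)]
}

#' @rdname prevalence_series
#' @return `sad_series`: yearly total attributable deaths named by year.
#' @export
sad_series <- function(result) {
  setNames(result$sads$total, result$sads$year)
}

record_prevalence <- function(state, year) {
  rows <- list()
  i <- 0L
  for (g in names(PREVALENCE_GROUPS)) {
    rng <- PREVALENCE_GROUPS[[g]]
    for (gd in c("male", "female", "both")) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        year = year, group = g, gender = gd,
        value = compute_prevalence(state, rng[1], rng[2], gd))
    }
  }
  do.call(rbind, rows)
}

#' Run one scenario
#'
#' Deterministically composes the four model parts year by year from the
#' bundle's base year to `horizon`.  Within each simulated year the order of
#' operations is: policy effects (prevalence increment and flow-rate
#' adjustments), behavioural transitions (initiation, cessation, relapse),
#' status-specific mortality (from which attributable deaths are recorded),
#' then aging and births.
#'
#' @param bundle an input bundle, e.g. from [make_brazil_like_fixture()].
#' @param schedule a [policy_schedule()]; default: the bundle's schedule.
#' @param horizon last simulated year.
#' @param bound effect-size bound variant.
#' @param label scenario label stored in the result.
#' @param policies set `FALSE` to bypass the policy engine entirely (the
#'   counterfactual with a frozen schedule is identical).
#' @return a [scenario_result()].
#' @export
run_scenario <- function(bundle, schedule = NULL, horizon = 2050,
                         bound = c("central", "lower", "upper"),
                         label = "scenario", policies = TRUE) {
  bound <- match.arg(bound)
  if (horizon < bundle$base_year)
    stop("horizon precedes the base year", call. = FALSE)
  schedule <- schedule %||% bundle$schedule
  if (policies) schedule <- extend_schedule(schedule, horizon)
  state <- bundle$state
  rates0 <- bundle$rates
  ages <- bundle$ages
  years <- bundle$base_year:horizon
  eff_prev <- NULL
  prev_rec <- vector("list", length(years))
  sad_rec <- vector("list", length(years))
  for (i in seq_along(years)) {
    t <- years[i]
    if (t > bundle$base_year) {
      births <- sum(bundle$fertility * state_population(state)[, "female"])
      if (policies) {
        eff <- schedule_to_effects(schedule, t, bound, ages = ages)
        adj <- apply_effects(state, rates0, eff, eff_prev)
        state <- adj$state
        rates_t <- adj$rates
        eff_prev <- eff
      } else rates_t <- rates0
      state <- step_smoking_states(state, rates_t)
      sm <- partition_mortality_grid(state, bundle$mortality, bundle$rr)
      sad_grid <- compute_sads(state, sm)
      state <- apply_status_mortality(state, sm)
      state <- age_smoking_state(state, births, bundle$sex_ratio_male)
    } else {
      sm <- partition_mortality_grid(state, bundle$mortality, bundle$rr)
      sad_grid <- compute_sads(state, sm)
    }
    prev_rec[[i]] <- record_prevalence(state, t)
    sad_rec[[i]] <- data.frame(year = t,
                               male = sum(sad_grid[, "male"]),
                               female = sum(sad_grid[, "female"]),
                               total = sum(sad_grid))
  }
  scenario_result(label, bound,
                  prevalence = do.call(rbind, prev_rec),
                  sads = do.call(rbind, sad_rec))
}

#' Deaths averted by a policy scenario
#'
#' Attributable deaths under the counterfactual minus those under the policy
#' scenario, summed over the requested years (a single year gives that
#' year's count; a range gives the cumulative count).
#'
#' @param policy,counterfactual [scenario_result()]s run on identical inputs
#'   except for the schedule.
#' @param years year(s) to sum over; default: all shared years.
#' @return a count (may be negative if the "policy" scenario is worse).
#' @export
deaths_averted <- function(policy, counterfactual, years = NULL) {
  if (!identical(policy$years, counterfactual$years))
    stop("scenarios cover different horizons", call. = FALSE)
  years <- years %||% policy$years
  if (!all(years %in% policy$years))
    stop("requested years outside the simulated range", call. = FALSE)
  cf <- sad_series(counterfactual)[as.character(years)]
  po <- sad_series(policy)[as.character(years)]
  sum(cf - po)
}

#' Relative reduction of a prevalence (percent)
#'
#' `(reference - policy) / reference * 100`.
#'
#' @param policy_prev prevalence under the policy scenario.
#' @param reference_prev reference (e.g. counterfactual) prevalence; must be
#'   positive.
#' @return percent reduction (negative if prevalence rose).
#' @examples
#' relative_reduction(22.9, 43.3)  # ~47.1
#' @export
relative_reduction <- function(policy_prev, reference_prev) {
  if (any(reference_prev <= 0))
    stop("reference prevalence must be positive", call. = FALSE)
  (reference_prev - policy_prev) / reference_prev * 100
}

#' Decompose single-policy reductions into contribution shares
#'
#' Because policy effects combine multiplicatively, each policy's
#' contribution is expressed relative to the sum of all single-policy
#' reductions: `share_d = r_d / sum(r) * 100`.  Shares sum to 100 before
#' rounding.
#'
#' @param reductions named non-negative numeric vector of single-policy
#'   reductions (any common unit), at least one positive.
#' @return named vector of percent shares.
#' @examples
#' decompose_contributions(c(price = 27.1, smokefree = 7.6))
#' @export
decompose_contributions <- function(reductions) {
  if (anyNA(reductions) || any(reductions < 0))
    stop("reductions must be non-negative", call. = FALSE)
  tot <- sum(reductions)
  if (tot <= 0) stop("at least one reduction must be positive", call. = FALSE)
  reductions / tot * 100
}

#' Build an FCTC-consistent maximal-policy schedule
#'
#' Extends the schedule to `horizon` at its final levels (the status quo),
#' then from `start_year` applies the full policy set: a tax rise from 60%
#' to 75% of retail price (full pass-through at constant pre-tax price gives
#' a price multiplier of (1-0.60)/(1-0.75) = 1.6), total smoke-free air laws
#' with full enforcement, a comprehensive and fully enforced marketing ban,
#' a high-intensity media campaign, strong warnings, complete cessation
#' treatment, and strongly enforced youth access restrictions.
#'
#' @param schedule a [policy_schedule()] covering the status-quo years.
#' @param start_year first year of the new policies.
#' @param horizon last simulated year.
#' @param price_multiplier price ratio applied at `start_year` (default
#'   `0.40 / 0.25`).
#' @return a `policy_schedule`.
#' @export
build_fctc_schedule <- function(schedule, start_year = 2011, horizon = 2050,
                                price_multiplier = 0.40 / 0.25) {
  s <- extend_schedule(schedule, horizon)
  d <- as.data.frame(s)
  if (!(start_year - 1L) %in% d$year)
    stop("schedule must cover the year before start_year", call. = FALSE)
  sel <- d$year >= start_year
  d$price_index[sel] <- d$price_index[d$year == start_year - 1L] *
    price_multiplier
  d$sf_worksite[sel] <- 1
  d$sf_restaurant[sel] <- 1
  d$sf_bar[sel] <- 1
  d$sf_other[sel] <- 1
  d$sf_enforcement[sel] <- 1
  d$media[sel] <- "high"
  d$marketing[sel] <- "comprehensive"
  d$marketing_enforcement[sel] <- 1
  d$warnings[sel] <- "strong"
  d$cessation_treatment[sel] <- 1
  d$youth_access[sel] <- "strong"
  policy_schedule(d, base_year = attr(schedule, "base_year"))
}

#' Run the standard scenario battery
#'
#' The counterfactual (levels frozen at the base year), the all-policies
#' scenario, and the seven single-policy scenarios (one domain follows its
#' schedule, the others stay at base-year levels), each under the requested
#' bound variants.  The counterfactual has no policy effects, hence no
#' bounds.
#'
#' @param bundle input bundle.
#' @param horizon last simulated year.
#' @param bounds subset of `c("central", "lower", "upper")`.
#' @return named list of [scenario_result()]s: `counterfactual`,
#'   `all_policies.<bound>`, and `<domain>.<bound>`.
#' @export
run_standard_scenarios <- function(bundle, horizon = 2050,
                                   bounds = "central") {
  out <- list(counterfactual = run_scenario(
    bundle, freeze_schedule(bundle$schedule), horizon,
    label = "counterfactual", policies = FALSE))
  for (b in bounds) {
    out[[paste("all_policies", b, sep = ".")]] <-
      run_scenario(bundle, bundle$schedule, horizon, bound = b,
                   label = "all_policies")
    for (d in POLICY_DOMAINS)
      out[[paste(d, b, sep = ".")]] <-
        run_scenario(bundle, single_policy_schedule(bundle$schedule, d),
                     horizon, bound = b, label = d)
  }
  out
}
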