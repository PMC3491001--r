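# Input validation, comparison-table rendering, long-format scenario CSV
# export, and a basic prevalence plot.

#' Validate an input bundle
#'
#' Checks every structural invariant the model relies on and returns one row
#' per violation (empty data frame iff the bundle is valid): non-negative
#' grids, rates and enforcement scores in range, smoking-state shares
#' summing to the population cell by cell, relative risks at least 1 and
#' non-increasing in years quit, relapse monotonicity, and schedule coverage.
#'
#' @param bundle a `fixture_bundle`-shaped list.
#' @return data frame with columns `location`, `message`.
#' @export
validate_inputs <- function(bundle) {
  bad <- list()
  note <- function(location, message)
    bad[[length(bad) + 1L]] <<- data.frame(location = location,
                                           message = message)
  try_quiet <- function(location, expr)
    tryCatch(expr, error = function(e) note(location, conditionMessage(e)))

  try_quiet("population", validate_ag_grid(bundle$population, "population"))
  try_quiet("mortality",
            validate_ag_grid(bundle$mortality, "mortality", max_value = 1))
  if (any(bundle$fertility < 0)) note("fertility", "negative fertility rate")
  if (bundle$sex_ratio_male < 0 || bundle$sex_ratio_male > 1)
    note("sex_ratio_male", "must be in [0, 1]")

  st <- bundle$state
  try_quiet("state", {
    validate_ag_grid(st$never, "never")
    validate_ag_grid(st$current, "current")
    if (min(st$former) < 0) stop("negative former-smoker count")
  })
  pop <- state_population(st)
  rel_err <- abs(pop - bundle$population) / pmax(1e-12, bundle$population)
  off <- which(rel_err > 1e-9, arr.ind = TRUE)
  for (i in seq_len(nrow(off)))
    note(sprintf("state[age=%s, %s]", rownames(pop)[off[i, 1]],
                 GENDERS[off[i, 2]]),
         "never + current + former does not match the population count")

  r <- bundle$rates
  try_quiet("rates", {
    validate_ag_grid(r$initiation, "initiation", max_value = 1)
    validate_ag_grid(r$cessation, "cessation", max_value = 1)
  })
  if (any(r$relapse < 0 | r$relapse > 1))
    note("rates$relapse", "relapse probabilities must be in [0, 1]")
  if (is.unsorted(rev(r$relapse)) && any(diff(r$relapse) > 1e-12))
    note("rates$relapse", "relapse should not increase with years quit")

  rr <- bundle$rr
  if (any(rr$rr_current < 1)) note("rr$rr_current", "relative risk below 1")
  if (any(rr$rr_former < 1)) note("rr$rr_former", "relative risk below 1")
  if (any(rr$rr_former[, , N_QUIT_BINS] > rr$rr_former[, , 1L] + 1e-12))
    note("rr$rr_former", "risk increases with years quit")

  try_quiet("schedule", {
    sc <- policy_schedule(as.data.frame(bundle$schedule),
                          base_year = attr(bundle$schedule, "base_year"))
    if (!bundle$base_year %in% sc$year)
      stop("schedule does not cover the base year")
  })
  if (length(bad) == 0L)
    return(data.frame(location = character(), message = character()))
  do.call(rbind, bad)
}

#' Render a scenario comparison table
#'
#' Rows are scenarios, columns are years: adult (18+) prevalence in percent
#' rounded to one decimal, and — when a scenario named `counterfactual` is
#' present — a deaths-averted block (counterfactual minus scenario
#' attributable deaths that year, rounded to integers).  Values are rounded
#' only here, at the rendering boundary.
#'
#' @param results named list of [scenario_result()]s.
#' @param years calendar years to tabulate.
#' @return data frame with columns `quantity`, `scenario`, one column per
#'   year.
#' @export
render_comparison_table <- function(results, years = NULL) {
  if (length(results) == 0L) stop("no scenarios to render", call. = FALSE)
  years <- years %||% range_years(results)
  rows <- lapply(names(results), function(nm) {
    p <- prevalence_series(results[[nm]])[as.character(years)]
    cbind(data.frame(quantity = "prevalence_pct", scenario = nm),
          as.data.frame(as.list(setNames(round(100 * p, 1), years)),
                        check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  if ("counterfactual" %in% names(results)) {
    cf <- sad_series(results$counterfactual)
    for (nm in setdiff(names(results), "counterfactual")) {
      av <- cf[as.character(years)] -
        sad_series(results[[nm]])[as.character(years)]
      out <- rbind(out, cbind(
        data.frame(quantity = "deaths_averted", scenario = nm),
        as.data.frame(as.list(setNames(round(av), years)),
                      check.names = FALSE)))
    }
  }
  rownames(out) <- NULL
  out
}

range_years <- function(results) {
  yrs <- results[[1L]]$years
  yrs[yrs %% 10 == 0 | yrs == min(yrs) | yrs == max(yrs)]
}

#' Write / read scenario results as long-format CSV
#'
#' One row per `scenario, bound, year, metric, group, value`: prevalence for
#' every age group x gender (as proportions) and attributable deaths
#' (unrounded).  The reader returns the long data frame; every derived
#' number in the rendered tables is recomputable from it.
#'
#' @param results named list of [scenario_result()]s.
#' @param path file path.
#' @return the writer returns `path` invisibly; the reader a data frame.
#' @export
write_scenario_csv <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    p <- r$prevalence
    prev <- data.frame(scenario = nm, bound = r$bound, year = p$year,
                       metric = "prevalence",
                       group = paste(p$group, p$gender, sep = "|"),
                       value = p$value)
    s <- r$sads
    sads <- data.frame(scenario = nm, bound = r$bound,
                       year = rep(s$year, 3L), metric = "sads",
                       group = rep(c("male", "female", "total"),
                                   each = nrow(s)),
                       value = c(s$male, s$female, s$total))
    rbind(prev, sads)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario_csv
#' @export
read_scenario_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plot adult prevalence trajectories
#'
#' Base-graphics line chart of 18+ prevalence for each scenario.
#'
#' @param results named list of [scenario_result()]s.
#' @param group,gender series selector, see [prevalence_series()].
#' @return invisibly, the matrix of plotted series.
#' @export
plot_prevalence <- function(results, group = "18+", gender = "both") {
  series <- sapply(results, function(r)
    prevalence_series(r, group, gender))
  yrs <- results[[1L]]$years
  graphics::matplot(yrs, 100 * series, type = "l", lty = 1,
                    xlab = "year", ylab = sprintf("prevalence %s (%%)", group))
  graphics::legend("topright", legend = names(results), lty = 1,
                   col = seq_along(results), bty = "n", cex = 0.8)
  invisible(series)
}
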