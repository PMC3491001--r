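# Demographic projection: births and deaths by single age and gender.

#' Demographic rates
#'
#' Annual fertility and all-cause mortality on a shared age grid.  Rates are
#' annual probabilities, not instantaneous hazards; within a simulated year
#' the order of events is deaths, then aging, then births.
#'
#' @param fertility births per woman per year, by maternal age (vector, one
#'   entry per age of the grid; non-negative).
#' @param mortality probability of dying within the year, age x gender grid
#'   in `[0, 1]` (the top bin may be 1).
#' @param sex_ratio_male fraction of births that are male.
#' @return an object of class `demographic_rates`.
#' @export
demographic_rates <- function(fertility, mortality, sex_ratio_male = 0.512) {
  validate_ag_grid(mortality, "mortality", max_value = 1)
  fertility <- as.numeric(fertility)
  if (length(fertility) != nrow(mortality))
    stop("fertility must have one entry per age of the mortality grid",
         call. = FALSE)
  if (anyNA(fertility) || any(fertility < 0))
    stop("negative or missing fertility rate", call. = FALSE)
  if (sex_ratio_male < 0 || sex_ratio_male > 1)
    stop("sex_ratio_male must be in [0, 1]", call. = FALSE)
  structure(list(fertility = fertility, mortality = mortality,
                 sex_ratio_male = sex_ratio_male),
            class = "demographic_rates")
}

#' Project a population forward one year
#'
#' Each cohort survives mortality and ages one year; the top bin accumulates
#' its own survivors; births (fertility applied to start-of-year female
#' counts) enter at age 0, split by the sex ratio at birth.
#'
#' @param pop age x gender grid of counts.
#' @param rates a [demographic_rates()] object on the same age grid.
#' @return next-year grid, with attributes `deaths` (grid) and `births`
#'   (total) so that `deaths + survivors == pop` cell by cell.
#' @examples
#' pop <- ag_grid(100, ages = 0:2)
#' mort <- ag_grid(0.1, ages = 0:2)
#' r <- demographic_rates(c(0, 0.5, 0), mort, sex_ratio_male = 0.5)
#' evolve_population(pop, r)
#' @export
evolve_population <- function(pop, rates) {
  validate_ag_grid(pop, "population")
  if (!inherits(rates, "demographic_rates"))
    stop("rates must be a demographic_rates object", call. = FALSE)
  check_same_grid(pop, rates$mortality, "population and mortality")
  surv <- pop * (1 - rates$mortality)
  deaths <- pop - surv
  births <- sum(rates$fertility * pop[, "female"])
  nxt <- shift_up(surv)
  nxt[1, "male"] <- births * rates$sex_ratio_male
  nxt[1, "female"] <- births * (1 - rates$sex_ratio_male)
  attr(nxt, "deaths") <- deaths
  attr(nxt, "births") <- births
  nxt
}
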