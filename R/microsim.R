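# Stochastic microsimulation oracles.  Each compartment's outflow is drawn
# with binomial sampling, which is distributionally identical to simulating
# every individual with Bernoulli transitions; the deterministic compartment
# model is the expectation of these runs.

#' Microsimulate a single cohort through the smoking Markov chain
#'
#' Follows `n` individuals of one gender from `age0` for `years` annual
#' steps, drawing initiation, cessation, and relapse transitions at the same
#' rates the deterministic model uses (no mortality: the chain alone).
#'
#' @param n cohort size.
#' @param age0 starting age.
#' @param years number of annual steps.
#' @param start named probabilities `never`, `current`, plus optionally
#'   `former` (length 16) of the starting distribution.
#' @param rates a [transition_rates()] object whose grid covers
#'   `age0..age0+years`.
#' @param gender `"male"` or `"female"` (rates column to follow).
#' @param seed RNG seed.
#' @return matrix `(years + 1) x 18`: counts in never, current, former bins
#'   1..16 after each step (row 1 = start).
#' @export
simulate_smoking_microcohort <- function(n, age0, years, start, rates,
                                         gender = "male", seed = 1L) {
  set.seed(seed)
  probs <- c(start$never, start$current,
             if (is.null(start$former)) rep(0, N_QUIT_BINS) else start$former)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("starting probabilities must sum to 1", call. = FALSE)
  counts <- as.vector(rmultinom(1L, n, probs))
  ages <- ag_ages(rates$initiation)
  out <- matrix(0L, years + 1L, 2L + N_QUIT_BINS,
                dimnames = list(step = 0:years,
                                state = c("never", "current", QUIT_BIN_LABELS)))
  out[1L, ] <- counts
  for (y in seq_len(years)) {
    age <- age0 + y - 1L
    row <- match(age, ages)
    if (is.na(row)) stop("rates grid does not cover age ", age, call. = FALSE)
    i_rate <- rates$initiation[row, gender]
    c_rate <- rates$cessation[row, gender]
    never <- counts[1L]; current <- counts[2L]; former <- counts[3:18]
    new_smokers <- rbinom(1L, never, i_rate)
    quits <- rbinom(1L, current, c_rate)
    relapses <- rbinom(N_QUIT_BINS, former, rates$relapse)
    stay <- former - relapses
    former2 <- c(quits, stay[1:14], stay[15L] + stay[16L])
    counts <- c(never - new_smokers,
                current - quits + new_smokers + sum(relapses),
                former2)
    out[y + 1L, ] <- counts
  }
  out
}

#' One stochastic replicate of the demographic projection
#'
#' Deaths are binomial draws per cell and births binomial draws per maternal
#' age, with a binomial sex split — the individual-level counterpart of
#' [evolve_population()], whose output is the mean of these replicates.
#'
#' @param pop age x gender grid of (integer) counts.
#' @param rates a [demographic_rates()] object.
#' @param seed RNG seed.
#' @return next-year grid of integer counts.
#' @export
simulate_population_micro <- function(pop, rates, seed = 1L) {
  set.seed(seed)
  n <- nrow(pop)
  deaths <- matrix(rbinom(2L * n, round(pop), as.vector(rates$mortality)),
                   n, 2L, dimnames = dimnames(pop))
  surv <- round(pop) - deaths
  births <- sum(rbinom(n, round(pop[, "female"]), pmin(1, rates$fertility)))
  boys <- rbinom(1L, births, rates$sex_ratio_male)
  nxt <- shift_up(surv)
  nxt[1L, ] <- c(boys, births - boys)
  nxt
}
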