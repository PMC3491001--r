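# Smoking-attributable mortality: partition all-cause mortality by smoking
# status with relative risks, then attribute the excess among current and
# former smokers.

#' Relative risks of death by smoking status
#'
#' All-cause mortality relative risks (never smoker = 1) for current smokers
#' by age x gender, and for former smokers additionally by years-quit bin.
#' Former-smoker risk must be non-increasing in years quit (risk recedes
#' toward the never-smoker level after quitting).
#'
#' @param rr_current age x gender grid, all values >= 1.
#' @param rr_former age x gender x years-quit array (16 bins), >= 1,
#'   with `rr_former[,,16] <= rr_former[,,1]`.
#' @return an object of class `relative_risks`.
#' @export
relative_risks <- function(rr_current, rr_former) {
  validate_ag_grid(rr_current, "rr_current")
  if (any(rr_current < 1)) stop("rr_current must be >= 1", call. = FALSE)
  if (!is.array(rr_former) || length(dim(rr_former)) != 3L ||
      !identical(dim(rr_former)[1:2], dim(rr_current)) ||
      dim(rr_former)[3L] != N_QUIT_BINS)
    stop("rr_former must be an age x gender x ", N_QUIT_BINS, " array",
         call. = FALSE)
  if (any(rr_former < 1)) stop("rr_former must be >= 1", call. = FALSE)
  if (any(rr_former[, , N_QUIT_BINS] > rr_former[, , 1L] + 1e-12))
    stop("rr_former must not increase with years quit", call. = FALSE)
  structure(list(rr_current = rr_current, rr_former = rr_former),
            class = "relative_risks")
}

#' Default relative-risk schedule
#'
#' A packaged synthetic default: current-smoker relative risk `rr` at ages 30
#' and above (1 below, where deaths are not attributed), and former-smoker
#' risk interpolating linearly from `rr` at quit-bin 1 down to 1 at the 16+
#' bin.  A stand-in for cohort-study estimates; fully configurable.
#'
#' @param rr current-smoker relative risk at ages 30+ (about 2.1 in US
#'   cohort studies; about 1.6 in some Asian cohorts).
#' @param ages age grid.
#' @param min_age youngest age carrying excess risk.
#' @return a [relative_risks()] object.
#' @export
default_relative_risks <- function(rr = 2.1, ages = DEFAULT_AGES,
                                   min_age = 30L) {
  cur <- ag_grid(1, ages = ages)
  cur[ages >= min_age, ] <- rr
  former <- array(1, dim = c(length(ages), 2L, N_QUIT_BINS))
  for (k in seq_len(N_QUIT_BINS))
    former[, , k] <- 1 + (cur - 1) * (N_QUIT_BINS - k) / (N_QUIT_BINS - 1)
  relative_risks(cur, former)
}

#' Partition all-cause mortality by smoking status (one cell)
#'
#' Solves for the never-smoker mortality rate `m_never` such that the
#' share-weighted status-specific rates recombine to the overall rate:
#' `m_never = m / (p_never + rr_cur * p_cur + sum_k rr_former_k * p_former_k)`,
#' with `m_current = rr_cur * m_never` and `m_former_k = rr_former_k * m_never`.
#'
#' @param overall_mortality all-cause annual death probability of the cell.
#' @param shares list with elements `never`, `current` (scalars) and `former`
#'   (vector over quit bins); must sum to 1.
#' @param rr list with elements `current` (scalar >= 1) and `former`
#'   (vector over quit bins).
#' @return list of status-specific rates `never`, `current`, `former`.
#' @examples
#' partition_mortality(0.012, list(never = 0.5, current = 0.5, former = 0),
#'                     list(current = 2, former = 1))
#' @export
partition_mortality <- function(overall_mortality, shares, rr) {
  tot <- shares$never + shares$current + sum(shares$former)
  if (abs(tot - 1) > 1e-6)
    stop("smoking-status shares must sum to 1", call. = FALSE)
  if (overall_mortality < 0 || overall_mortality > 1)
    stop("overall mortality must be in [0, 1]", call. = FALSE)
  denom <- shares$never + rr$current * shares$current +
    sum(rr$former * shares$former)
  m_never <- overall_mortality / denom
  m_current <- rr$current * m_never
  if (m_current > 1)
    stop("clamping error: current-smoker mortality exceeds 1", call. = FALSE)
  list(never = m_never, current = m_current, former = rr$former * m_never)
}

# Vectorised partition across the whole grid.  Cells with no population get
# the overall rate for every status (the attribution is vacuous there).
partition_mortality_grid <- function(state, mortality, rr) {
  pop <- state_population(state)
  wsum <- state$never + rr$rr_current * state$current
  wf <- state$former * rr$rr_former
  for (k in seq_len(N_QUIT_BINS)) wsum <- wsum + wf[, , k]
  m_never <- ifelse(pop > 0, mortality * pop / wsum, mortality)
  m_former <- rr$rr_former * as.vector(m_never)   # recycles age x gender
  list(never = m_never, current = rr$rr_current * m_never, former = m_former)
}

#' Smoking-attributable deaths for one year
#'
#' Excess deaths among current and former smokers relative to the
#' never-smoker rate of the same cell:
#' `SAD = current * (m_cur - m_never) + sum_k former_k * (m_former_k - m_never)`.
#' Deaths are attributed only at ages `min_age` and above (default 30, the
#' age from which excess risk is carried).
#'
#' @param state a [smoking_state()].
#' @param status_mortality status-specific rates for the same state, from
#'   [partition_mortality_grid] (list of `never`, `current`, `former`).
#' @param min_age youngest age at which deaths are attributed.
#' @return age x gender grid of attributable deaths (non-negative when all
#'   relative risks are >= 1).
#' @export
compute_sads <- function(state, status_mortality, min_age = 30L) {
  sm <- status_mortality
  sad <- state$current * (sm$current - sm$never)
  exf <- state$former * (sm$former - array(as.vector(sm$never),
                                           dim = dim(state$former)))
  for (k in seq_len(N_QUIT_BINS)) sad <- sad + exf[, , k]
  if (min(sad) < -1e-9 * max(1, abs(sad)))
    stop("negative attributable deaths: relative risk below 1?", call. = FALSE)
  sad[ag_ages(state$never) < min_age, ] <- 0
  sad
}

# Survive each compartment with its status-specific rate; returns the state
# with a "deaths" attribute (grid of total deaths).
apply_status_mortality <- function(state, status_mortality) {
  sm <- status_mortality
  never <- state$never * (1 - sm$never)
  current <- state$current * (1 - sm$current)
  former <- state$former * (1 - sm$former)
  out <- smoking_state(never, current, former)
  attr(out, "deaths") <- state_population(state) - state_population(out)
  out
}

#' Sum a yearly series of attributable deaths over an inclusive year range
#'
#' @param yearly_sads numeric vector named by calendar year.
#' @param year_lo,year_hi inclusive range; every year must be present.
#' @return the total count.
#' @examples
#' cumulative_sads(c(`1989` = 100, `1990` = 100), 1989, 1990)
#' @export
cumulative_sads <- function(yearly_sads, year_lo, year_hi) {
  yrs <- as.character(year_lo:year_hi)
  if (!all(yrs %in% names(yearly_sads)))
    stop("series is missing years in [", year_lo, ", ", year_hi, "]",
         call. = FALSE)
  sum(yearly_sads[yrs])
}
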