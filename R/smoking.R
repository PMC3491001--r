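# Smoking-state accounting and the first-order Markov transition step:
# never -> current (initiation, through age INIT_AGE_MAX), current -> former
# bin 1 (cessation, above INIT_AGE_MAX), former bin k -> current (relapse,
# duration-dependent) else advance to bin k+1 (top bin absorbing).

INIT_AGE_MAX <- 29L
N_QUIT_BINS <- 16L
QUIT_BIN_LABELS <- c(as.character(1:15), "16+")

empty_former <- function(ages) {
  array(0, dim = c(length(ages), 2L, N_QUIT_BINS),
        dimnames = list(age = as.character(ages), gender = GENDERS,
                        years_quit = QUIT_BIN_LABELS))
}

#' Smoking-state container
#'
#' Counts of never, current, and former smokers (the latter by years since
#' quitting: yearly bins 1..15 plus an absorbing 16+ bin) on an age x gender
#' grid.  `never + current + sum(former)` is the population of each cell.
#'
#' @param never,current age x gender grids of counts.
#' @param former age x gender x years-quit array (16 bins); defaults to zero.
#' @return an object of class `smoking_state`.
#' @export
smoking_state <- function(never, current, former = NULL) {
  validate_ag_grid(never, "never")
  validate_ag_grid(current, "current")
  check_same_grid(never, current, "never and current")
  if (is.null(former)) former <- empty_former(ag_ages(never))
  if (!is.array(former) || length(dim(former)) != 3L ||
      !identical(dim(former), c(nrow(never), 2L, N_QUIT_BINS)))
    stop("former must be an age x gender x ", N_QUIT_BINS, " array",
         call. = FALSE)
  # tolerate float-level negatives from chained arithmetic, reject real ones
  tol <- -1e-9 * max(1, never, current, former)
  if (anyNA(former) || min(former) < tol)
    stop("negative count in former-smoker bins", call. = FALSE)
  former[former < 0] <- 0
  dimnames(former) <- list(age = rownames(never), gender = GENDERS,
                           years_quit = QUIT_BIN_LABELS)
  structure(list(never = never, current = current, former = former),
            class = "smoking_state")
}

#' @rdname smoking_state
#' @param state a `smoking_state`.
#' @return `former_totals`: grid of former smokers summed over quit bins;
#'   `state_population`: grid of total counts.
#' @export
former_totals <- function(state) {
  ft <- state$former[, , 1L]
  for (k in 2:N_QUIT_BINS) ft <- ft + state$former[, , k]
  ft
}

#' @rdname smoking_state
#' @export
state_population <- function(state) {
  state$never + state$current + former_totals(state)
}

#' Transition rates of the smoking Markov chain
#'
#' Initiation applies only through age `init_age_max` (default 29, where
#' prevalence levels off); cessation is tracked only above that age; relapse
#' probability depends on the years-since-quitting bin and should be
#' non-increasing in duration.
#'
#' @param initiation per-age (x gender) annual probability that a never
#'   smoker starts; grid, or vector by age recycled across genders.
#' @param cessation per-age (x gender) annual first-time quit probability.
#' @param relapse length-16 vector of annual return-to-smoking probabilities
#'   by years-quit bin.
#' @param ages age grid the rates live on (used when vectors are given).
#' @param init_age_max oldest age at which initiation occurs.
#' @return an object of class `transition_rates`.
#' @export
transition_rates <- function(initiation, cessation, relapse,
                             ages = DEFAULT_AGES, init_age_max = INIT_AGE_MAX) {
  as_rate_grid <- function(x, what) {
    if (!is.matrix(x)) {
      x <- as.numeric(x)
      if (!length(x) %in% c(1L, length(ages)))
        stop(what, " must be a grid, a scalar, or one value per age",
             call. = FALSE)
      x <- ag_grid(rep(x, length.out = length(ages)), ages = ages)
    }
    validate_ag_grid(x, what, max_value = 1)
    x
  }
  initiation <- as_rate_grid(initiation, "initiation")
  cessation <- as_rate_grid(cessation, "cessation")
  check_same_grid(initiation, cessation, "initiation and cessation")
  ag <- ag_ages(initiation)
  if (any(initiation[ag > init_age_max, ] > 0))
    stop("initiation must be zero above age ", init_age_max, call. = FALSE)
  if (any(cessation[ag <= init_age_max, ] > 0))
    stop("cessation must be zero at or below age ", init_age_max, call. = FALSE)
  relapse <- as.numeric(relapse)
  if (length(relapse) == 1L) relapse <- rep(relapse, N_QUIT_BINS)
  if (length(relapse) != N_QUIT_BINS || any(relapse < 0 | relapse > 1))
    stop("relapse must be ", N_QUIT_BINS, " probabilities in [0, 1]",
         call. = FALSE)
  structure(list(initiation = initiation, cessation = cessation,
                 relapse = relapse, init_age_max = as.integer(init_age_max)),
            class = "transition_rates")
}

#' Derive net initiation rates from consecutive prevalence curves
#'
#' Initiation at age a is measured as the rise of the prevalence curve over
#' one cohort-year: `max(0, prev_now(a) - prev_last(a - 1))`, converted to a
#' probability among never smokers by dividing by the never-smoker share.
#' Negative differences (a declining curve) are clamped to zero so that state
#' counts stay non-negative.
#'
#' @param prev_now prevalence by age this year (vector over ages 0..A).
#' @param prev_last prevalence by age last year (same ages).
#' @param never_share share of never smokers by age; default `1 - prev_now`
#'   (appropriate where former smokers are negligible, i.e. at young ages).
#' @return vector of initiation probabilities, same length as `prev_now`.
#' @examples
#' # 10% smoke at 16 this year, 8% smoked at 15 last year, 90% never smokers:
#' derive_initiation_rates(c(0.08, 0.10), c(0.08, 0.10))[2]  # 0.02 / 0.90
#' @export
derive_initiation_rates <- function(prev_now, prev_last,
                                    never_share = NULL) {
  if (length(prev_now) != length(prev_last))
    stop("prevalence curves must cover the same ages", call. = FALSE)
  if (any(prev_now < 0 | prev_now > 1) || any(prev_last < 0 | prev_last > 1))
    stop("prevalence outside [0, 1]", call. = FALSE)
  if (is.null(never_share)) never_share <- 1 - prev_now
  net <- pmax(0, prev_now - c(0, prev_last[-length(prev_last)]))
  out <- ifelse(never_share > 0, net / never_share, 0)
  pmin(1, out)
}

#' Advance smoking states one Markov step
#'
#' Pure behavioural transitions (no mortality, no aging — those are applied
#' by the caller, see [run_scenario()]): never smokers initiate (ages up to
#' the initiation cutoff), current smokers quit into former bin 1, former
#' smokers either relapse back to current with the bin-specific probability
#' or advance one duration bin (16+ absorbing).
#'
#' @param state a [smoking_state()].
#' @param rates a [transition_rates()] object on the same age grid.
#' @return the next `smoking_state`; total counts are conserved cell by cell.
#' @export
step_smoking_states <- function(state, rates) {
  stopifnot(inherits(state, "smoking_state"),
            inherits(rates, "transition_rates"))
  check_same_grid(state$never, rates$initiation, "state and rates")
  new_smokers <- state$never * rates$initiation
  quits <- state$current * rates$cessation
  f <- state$former
  rel <- sweep(f, 3L, rates$relapse, `*`)
  stay <- f - rel
  nf <- empty_former(ag_ages(state$never))
  nf[, , 1L] <- quits
  nf[, , 2:15] <- stay[, , 1:14]
  nf[, , 16L] <- stay[, , 15L] + stay[, , 16L]
  relapsed <- rel[, , 1L]
  for (k in 2:N_QUIT_BINS) relapsed <- relapsed + rel[, , k]
  smoking_state(never = state$never - new_smokers,
                current = state$current - quits + new_smokers + relapsed,
                former = nf)
}

# Age every compartment one year; births enter the never-smoker pool at age 0.
age_smoking_state <- function(state, births = 0, sex_ratio_male = 0.512) {
  never <- shift_up(state$never)
  never[1L, ] <- births * c(sex_ratio_male, 1 - sex_ratio_male)
  current <- shift_up(state$current)
  f <- state$former
  n <- dim(f)[1L]
  nf <- f * 0
  nf[2:n, , ] <- f[1:(n - 1), , ]
  nf[n, , ] <- nf[n, , ] + f[n, , ]
  smoking_state(never, current, nf)
}

#' Smoking prevalence over an age range
#'
#' Current smokers divided by total population, aggregated over the selected
#' ages and gender(s) (count-weighted by construction).
#'
#' @param state a [smoking_state()].
#' @param age_lo,age_hi inclusive age range (default adults 18+).
#' @param gender `"male"`, `"female"`, or `"both"`.
#' @return a proportion in `[0, 1]`.
#' @export
compute_prevalence <- function(state, age_lo = 18, age_hi = Inf,
                               gender = c("both", "male", "female")) {
  gender <- match.arg(gender)
  cols <- if (gender == "both") GENDERS else gender
  sel <- ag_ages(state$never) >= age_lo & ag_ages(state$never) <= age_hi
  if (!any(sel)) stop("empty age selection", call. = FALSE)
  tot <- sum(state_population(state)[sel, cols])
  if (tot <= 0) stop("empty selection: no population in range", call. = FALSE)
  sum(state$current[sel, cols]) / tot
}

#' Read/write a smoking state as CSV, or round-trip it through JSON
#'
#' CSV columns: `age, gender, state, years_quit, count` (`years_quit` empty
#' except for former smokers).  The JSON form is a faithful checkpoint of the
#' full state.
#'
#' @param state a [smoking_state()].
#' @param path file path.
#' @return readers return a `smoking_state`; writers return `path` invisibly.
#' @export
write_smoking_state_csv <- function(state, path) {
  ages <- ag_ages(state$never)
  base <- function(m, lab) data.frame(
    age = rep(ages, 2L), gender = rep(GENDERS, each = length(ages)),
    state = lab, years_quit = NA_character_, count = as.vector(m))
  d <- rbind(base(state$never, "never"), base(state$current, "current"))
  for (k in seq_len(N_QUIT_BINS)) {
    dk <- base(state$former[, , k], "former")
    dk$years_quit <- QUIT_BIN_LABELS[k]
    d <- rbind(d, dk)
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_smoking_state_csv
#' @export
read_smoking_state_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(years_quit = "character"))
  ages <- sort(unique(as.integer(d$age)))
  grab <- function(rows) {
    g <- ag_grid(0, ages = ages)
    g[cbind(match(as.integer(d$age[rows]), ages),
            match(d$gender[rows], GENDERS))] <- d$count[rows]
    g
  }
  never <- grab(d$state == "never")
  current <- grab(d$state == "current")
  former <- empty_former(ages)
  for (k in seq_len(N_QUIT_BINS)) {
    rows <- d$state == "former" & d$years_quit == QUIT_BIN_LABELS[k]
    former[, , k] <- grab(rows)
  }
  smoking_state(never, current, former)
}

#' @rdname write_smoking_state_csv
#' @export
state_to_json <- function(state, path = NULL) {
  obj <- list(ages = ag_ages(state$never),
              never = as.vector(state$never),
              current = as.vector(state$current),
              former = as.vector(state$former))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' @rdname write_smoking_state_csv
#' @param json JSON string or path produced by [state_to_json()].
#' @export
state_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  ages <- as.integer(obj$ages)
  n <- length(ages)
  smoking_state(
    never = ag_grid(obj$never, ages = ages),
    current = ag_grid(obj$current, ages = ages),
    former = array(obj$former, dim = c(n, 2L, N_QUIT_BINS)))
}
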