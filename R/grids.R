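# Age x gender grids: the elementary container for counts and rates.
# A grid is a plain numeric matrix with age rownames (single years, ascending,
# top bin open-ended) and columns "male", "female".

GENDERS <- c("male", "female")
DEFAULT_AGES <- 0:100

#' Construct an age x gender grid
#'
#' Grids are ordinary numeric matrices with one row per single year of age
#' (ascending; the last age is an open-ended top bin) and columns `male`,
#' `female`.  All model quantities — population counts, mortality rates,
#' smoking-state counts — live on such grids.
#'
#' @param values numeric; recycled into the matrix (age-major).
#' @param ages integer vector of ages, default `0:100` (100 = open top bin).
#' @return a numeric matrix with age rownames and gender colnames.
#' @examples
#' pop <- ag_grid(1000)            # 1000 in every cell
#' ag_grid(0, ages = 40:45)
#' @export
ag_grid <- function(values = 0, ages = DEFAULT_AGES) {
  g <- matrix(values, nrow = length(ages), ncol = 2L,
              dimnames = list(age = as.character(ages), gender = GENDERS))
  validate_ag_grid(g)
  g
}

#' Validate an age x gender grid
#'
#' @param g object to check.
#' @param what label used in error messages.
#' @param max_value optional upper bound (e.g. 1 for probabilities).
#' @return `g`, invisibly; errors describe the violation.
#' @export
validate_ag_grid <- function(g, what = "grid", max_value = Inf) {
  if (!is.matrix(g) || !is.numeric(g) || ncol(g) != 2L)
    stop(what, " must be a numeric age x gender matrix with two columns",
         call. = FALSE)
  if (!identical(colnames(g), GENDERS))
    stop(what, " columns must be 'male', 'female' in that order", call. = FALSE)
  ages <- suppressWarnings(as.integer(rownames(g)))
  if (is.null(rownames(g)) || anyNA(ages) || is.unsorted(ages, strictly = TRUE))
    stop(what, " must have strictly increasing integer age rownames",
         call. = FALSE)
  if (anyNA(g) || any(g < 0))
    stop(what, " has negative or missing cells", call. = FALSE)
  if (any(g > max_value))
    stop(what, " has cells above ", max_value, call. = FALSE)
  invisible(g)
}

#' @rdname ag_grid
#' @export
ag_ages <- function(g) as.integer(rownames(g))

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)) || !identical(rownames(a), rownames(b)))
    stop(what, " are defined on different age grids", call. = FALSE)
  invisible(TRUE)
}

# Shift a grid up one age; the top bin accumulates its own survivors.
shift_up <- function(m) {
  n <- nrow(m)
  r <- m * 0
  r[2:n, ] <- m[1:(n - 1), ]
  r[n, ] <- r[n, ] + m[n, ]
  r
}

#' Read / write age x gender tables as CSV
#'
#' Long format with header `age,gender,value` (UTF-8, RFC 4180).
#'
#' @param path file path.
#' @return `read_age_gender_csv` returns a grid; the writer returns `path`
#'   invisibly.
#' @export
read_age_gender_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "gender", "value")
  if (!all(need %in% names(d)))
    stop("'", path, "' must have columns age, gender, value", call. = FALSE)
  ages <- sort(unique(as.integer(d$age)))
  g <- ag_grid(0, ages = ages)
  g[cbind(match(as.integer(d$age), ages), match(d$gender, GENDERS))] <- d$value
  validate_ag_grid(g, basename(path))
  g
}

#' @rdname read_age_gender_csv
#' @param g an age x gender grid.
#' @export
write_age_gender_csv <- function(g, path) {
  validate_ag_grid(g)
  d <- data.frame(age = rep(ag_ages(g), times = 2L),
                  gender = rep(GENDERS, each = nrow(g)),
                  value = as.vector(g))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
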