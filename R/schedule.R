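# Policy schedules: one row per simulated year holding the levels of the
# seven policy domains, validated and serialisable as a per-year YAML config.

SCHEDULE_COLUMNS <- c("year", "price_index",
                      "sf_worksite", "sf_restaurant", "sf_bar", "sf_other",
                      "sf_enforcement",
                      "media", "marketing", "marketing_enforcement",
                      "warnings", "cessation_treatment", "youth_access")

DOMAIN_COLUMNS <- list(
  price = "price_index",
  smokefree = c("sf_worksite", "sf_restaurant", "sf_bar", "sf_other",
                "sf_enforcement"),
  media = "media",
  marketing = c("marketing", "marketing_enforcement"),
  warnings = "warnings",
  cessation_treatment = "cessation_treatment",
  youth_access = "youth_access")

MEDIA_LEVELS <- names(MEDIA_EFFECTS)
MARKETING_LEVELS <- names(MARKETING_EFFECTS)
WARNING_LEVELS <- names(WARNING_EFFECTS)
YOUTH_LEVELS <- names(YOUTH_EFFECTS)

#' Policy schedule
#'
#' A validated data frame with one row per contiguous simulated year and the
#' levels of all seven policy domains: `price_index` (real price relative to
#' the base year), the four additive smoke-free components (fractions in
#' `[0, 1]`) with an enforcement score, the mutually exclusive `media`,
#' `marketing`, `warnings` and `youth_access` level labels, marketing
#' enforcement, and the `cessation_treatment` availability fraction.
#'
#' @param df data frame with the columns above.
#' @param base_year reference year whose levels define "no policy change"
#'   (default: first year of `df`).
#' @return a `policy_schedule` (classed data frame with a `base_year`
#'   attribute).
#' @export
policy_schedule <- function(df, base_year = min(df$year)) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(SCHEDULE_COLUMNS, names(df))
  if (length(miss))
    stop("schedule is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$year), SCHEDULE_COLUMNS]
  if (anyDuplicated(df$year) ||
      !identical(as.integer(df$year), seq(min(df$year), max(df$year))))
    stop("schedule years must be contiguous and unique", call. = FALSE)
  if (!base_year %in% df$year)
    stop("base year ", base_year, " is not in the schedule", call. = FALSE)
  if (any(df$price_index <= 0))
    stop("price_index must be positive", call. = FALSE)
  chk01 <- function(col) {
    if (any(df[[col]] < 0 | df[[col]] > 1))
      stop(col, " must be in [0, 1]", call. = FALSE)
  }
  for (col in c("sf_worksite", "sf_restaurant", "sf_bar", "sf_other",
                "sf_enforcement", "marketing_enforcement",
                "cessation_treatment")) chk01(col)
  chklvl <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad))
      stop("unknown ", col, " level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  chklvl("media", MEDIA_LEVELS)
  chklvl("marketing", MARKETING_LEVELS)
  chklvl("warnings", WARNING_LEVELS)
  chklvl("youth_access", YOUTH_LEVELS)
  rownames(df) <- NULL
  structure(df, class = c("policy_schedule", "data.frame"),
            base_year = as.integer(base_year))
}

#' Derived schedules: extension, counterfactual freeze, single policy
#'
#' `extend_schedule` carries the last year's levels forward to `horizon`
#' (the status-quo extension).  `freeze_schedule` sets every year to the
#' base-year levels (the counterfactual).  `single_policy_schedule` keeps
#' one domain's trajectory and resets all other domains to base-year levels.
#'
#' @param schedule a [policy_schedule()].
#' @param horizon last simulated year.
#' @param domain one of the seven policy domain names.
#' @return a new `policy_schedule` with the same base year.
#' @export
extend_schedule <- function(schedule, horizon) {
  sc <- as.data.frame(schedule)
  last <- max(sc$year)
  if (horizon > last) {
    tail_row <- sc[sc$year == last, , drop = FALSE]
    add <- tail_row[rep(1L, horizon - last), , drop = FALSE]
    add$year <- seq(last + 1L, horizon)
    sc <- rbind(sc, add)
  }
  policy_schedule(sc, base_year = attr(schedule, "base_year"))
}

#' @rdname extend_schedule
#' @export
freeze_schedule <- function(schedule, horizon = NULL) {
  sc <- as.data.frame(schedule)
  base_year <- attr(schedule, "base_year")
  horizon <- horizon %||% max(sc$year)
  base <- sc[sc$year == base_year, , drop = FALSE]
  out <- base[rep(1L, horizon - min(sc$year) + 1L), , drop = FALSE]
  out$year <- seq(min(sc$year), horizon)
  policy_schedule(out, base_year = base_year)
}

#' @rdname extend_schedule
#' @export
single_policy_schedule <- function(schedule, domain) {
  if (!domain %in% POLICY_DOMAINS)
    stop("unknown policy domain '", domain, "'", call. = FALSE)
  sc <- as.data.frame(schedule)
  base_year <- attr(schedule, "base_year")
  base <- sc[sc$year == base_year, , drop = FALSE]
  for (d in setdiff(POLICY_DOMAINS, domain))
    for (col in DOMAIN_COLUMNS[[d]]) sc[[col]] <- base[[col]]
  policy_schedule(sc, base_year = base_year)
}

#' Read / write a policy schedule as a per-year YAML config
#'
#' The file holds `base_year` and a `years` list; each block gives the year
#' and any domain levels that changed (missing fields carry forward from the
#' previous year, so configs stay compact).  A machine-readable description
#' of the format ships at `system.file("extdata/schedule-schema.json",
#' package = "smokesim")`.
#'
#' @param schedule a [policy_schedule()].
#' @param path file path.
#' @return the reader returns a `policy_schedule`; the writer returns `path`
#'   invisibly.
#' @export
write_policy_schedule <- function(schedule, path) {
  sc <- as.data.frame(schedule)
  blocks <- lapply(seq_len(nrow(sc)), function(i) {
    r <- sc[i, ]
    list(year = as.integer(r$year),
         price_index = r$price_index,
         smokefree = list(worksite = r$sf_worksite,
                          restaurant = r$sf_restaurant,
                          bar = r$sf_bar, other = r$sf_other,
                          enforcement = r$sf_enforcement),
         media = r$media,
         marketing = list(level = r$marketing,
                          enforcement = r$marketing_enforcement),
         warnings = r$warnings,
         cessation_treatment = r$cessation_treatment,
         youth_access = r$youth_access)
  })
  yaml::write_yaml(list(base_year = attr(schedule, "base_year"),
                        years = blocks), path, precision = 15)
  invisible(path)
}

#' @rdname write_policy_schedule
#' @export
read_policy_schedule <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$base_year) || is.null(cfg$years) || !length(cfg$years))
    stop("'", path, "' must define base_year and a years list", call. = FALSE)
  prev <- NULL
  rows <- lapply(cfg$years, function(b) {
    if (is.null(b$year)) stop("every years block needs a year", call. = FALSE)
    sf <- b$smokefree %||% list()
    mk <- b$marketing %||% list()
    row <- data.frame(
      year = as.integer(b$year),
      price_index = b$price_index %||% prev$price_index %||% 1,
      sf_worksite = sf$worksite %||% prev$sf_worksite %||% 0,
      sf_restaurant = sf$restaurant %||% prev$sf_restaurant %||% 0,
      sf_bar = sf$bar %||% prev$sf_bar %||% 0,
      sf_other = sf$other %||% prev$sf_other %||% 0,
      sf_enforcement = sf$enforcement %||% prev$sf_enforcement %||% 0,
      media = b$media %||% prev$media %||% "none",
      marketing = mk$level %||% prev$marketing %||% "none",
      marketing_enforcement = mk$enforcement %||%
        prev$marketing_enforcement %||% 0,
      warnings = b$warnings %||% prev$warnings %||% "none",
      cessation_treatment = b$cessation_treatment %||%
        prev$cessation_treatment %||% 0,
      youth_access = b$youth_access %||% prev$youth_access %||% "none",
      stringsAsFactors = FALSE)
    prev <<- row
    row
  })
  df <- do.call(rbind, rows)
  # fill interior gaps by carrying the previous year forward
  full <- df[match(seq(min(df$year), max(df$year)), df$year), ]
  for (i in seq_len(nrow(full)))
    if (is.na(full$year[i])) full[i, ] <- full[i - 1L, ]
  full$year <- seq(min(df$year), max(df$year))
  policy_schedule(full, base_year = as.integer(cfg$base_year))
}
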