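#' Cause-specific mortality fraction distribution
#'
#' A named vector of cause fractions that must be non-negative and sum to
#' one (within 1e-9).
#'
#' @param fractions named numeric vector.
#' @return a validated `cause_distribution` (named numeric vector).
#' @export
cause_distribution <- function(fractions) {
  if (is.null(names(fractions)) || anyDuplicated(names(fractions))) {
    hv_stop("cause distribution needs unique cause names", "hierVA_input_error")
  }
  if (any(fractions < 0)) {
    hv_stop("cause fractions must be non-negative", "hierVA_input_error")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    hv_stop(sprintf("cause fractions sum to %.6f, not 1", sum(fractions)),
            "hierVA_input_error")
  }
  structure(as.numeric(fractions), names = names(fractions),
            class = "cause_distribution")
}

#' Mortality scenario specifications
#'
#' The four validation scenarios:
#' \describe{
#'   \item{high_u5mr_malaria}{high under-five mortality (U5MR > 35 deaths
#'     per 1000 live births) where malaria is endemic (> 5\% of under-five
#'     deaths due to malaria)}
#'   \item{high_u5mr_no_malaria}{U5MR > 35, malaria fraction <= 5\%}
#'   \item{moderate_u5mr}{U5MR between 20 and 35 per 1000}
#'   \item{general}{every cause fraction drawn uniformly between 5\% and
#'     40\%, then normalized to sum to one}
#' }
#'
#' @param name one of the four scenario names.
#' @param general_bounds lower/upper bound of the per-cause uniform draw in
#'   the general scenario.
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(name = c("high_u5mr_malaria", "high_u5mr_no_malaria",
                                   "moderate_u5mr", "general"),
                          general_bounds = c(0.05, 0.40)) {
  name <- match.arg(name)
  filter <- switch(name,
    high_u5mr_malaria    = function(u5mr, mf) u5mr > 35 & mf > 0.05,
    high_u5mr_no_malaria = function(u5mr, mf) u5mr > 35 & mf <= 0.05,
    moderate_u5mr        = function(u5mr, mf) u5mr >= 20 & u5mr <= 35,
    general              = NULL)
  structure(list(name = name, filter = filter,
                 general_bounds = if (name == "general") general_bounds),
            class = "scenario_spec")
}

#' Read a country CSMF table from CSV
#'
#' Columns: `country_id`, `age_group`, `u5mr` (under-five deaths per 1000
#' live births), `malaria_fraction` (fraction of under-five deaths due to
#' malaria), then one column per cause holding that country's CSMF.  Each
#' row's cause fractions must form a valid distribution.  A synthetic table
#' of plausible but fictional countries ships for testing
#' (`synthetic_country_csmf_neonate.csv`, `synthetic_country_csmf_child.csv`);
#' real WHO/CHERG estimates are user-supplied in the same layout.
#'
#' @param path CSV path, or `"neonate"`/`"child"` for the bundled synthetic
#'   tables.
#' @return a `country_csmf_table` (data frame with a `causes` attribute).
#' @export
read_country_table <- function(path) {
  if (path %in% c("neonate", "child")) {
    path <- hierva_example(sprintf("synthetic_country_csmf_%s.csv", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("country_id", "age_group", "u5mr", "malaria_fraction")
  if (!all(meta %in% names(df))) {
    hv_stop(sprintf("country table needs columns %s", paste(meta, collapse = ", ")),
            "hierVA_input_error")
  }
  causes <- setdiff(names(df), meta)
  if (length(causes) < 2L) {
    hv_stop("country table needs at least two cause columns",
            "hierVA_input_error")
  }
  if (any(df$u5mr <= 0)) hv_stop("u5mr must be positive", "hierVA_input_error")
  for (i in seq_len(nrow(df))) {
    cause_distribution(stats::setNames(as.numeric(df[i, causes]), causes))
  }
  structure(df, causes = causes, class = c("country_csmf_table", "data.frame"))
}

#' Country rows eligible under a scenario
#'
#' @param table a `country_csmf_table`.
#' @param scenario a [scenario_spec] (country-filter scenarios only).
#' @return the eligible rows of `table`.
#' @export
eligible_rows <- function(table, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(scenario$filter)) {
    hv_stop("the general scenario does not filter countries",
            "hierVA_usage_error")
  }
  keep <- scenario$filter(table$u5mr, table$malaria_fraction)
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    hv_stop(sprintf("no country rows eligible for scenario '%s'", scenario$name),
            "hierVA_scenario_error")
  }
  out
}

#' Draw a target cause distribution for a scenario
#'
#' Country scenarios pick one eligible country uniformly at random and
#' return its CSMF; the general scenario draws every cause fraction
#' uniformly on the configured bounds (default \[0.05, 0.40\]) and
#' normalizes the vector to sum to one.  Reproducible under `set.seed()`.
#'
#' @param scenario a [scenario_spec].
#' @param table a `country_csmf_table` (country scenarios).
#' @param causes character vector of cause ids (general scenario).
#' @return a [cause_distribution].
#' @export
draw_target_csmf <- function(scenario, table = NULL, causes = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (scenario$name == "general") {
    if (is.null(causes)) causes <- attr(table, "causes")
    if (is.null(causes) || length(causes) < 2L) {
      hv_stop("general scenario needs a cause list", "hierVA_usage_error")
    }
    raw <- stats::runif(length(causes), scenario$general_bounds[1],
                        scenario$general_bounds[2])
    return(cause_distribution(stats::setNames(raw / sum(raw), causes)))
  }
  rows <- eligible_rows(table, scenario)
  pick <- rows[sample.int(nrow(rows), 1L), , drop = FALSE]
  causes <- attr(table, "causes")
  cause_distribution(stats::setNames(as.numeric(pick[1, causes]), causes))
}

#' Restrict a target distribution to available causes
#'
#' Causes absent from the labelled pool cannot be resampled; their mass is
#' dropped and the remaining fractions rescaled to sum to one (relative
#' proportions preserved, unreported causes not considered).
#'
#' @param target a [cause_distribution].
#' @param available character vector of causes present in the pool.
#' @return a [cause_distribution] over `intersect(names(target), available)`.
#' @export
renormalize_over_available <- function(target, available) {
  keep <- intersect(names(target), available)
  if (length(keep) == 0L) {
    hv_stop("no target cause is available in the death pool",
            "hierVA_scenario_error")
  }
  kept <- unclass(target)[keep]
  if (sum(kept) <= 0) {
    hv_stop("available causes carry zero target mass", "hierVA_scenario_error")
  }
  cause_distribution(kept / sum(kept))
}

#' Integer death counts for a target distribution
#'
#' Largest-remainder apportionment of `n * fraction` per cause; counts sum
#' to `n` exactly and deviate from the exact share by less than one death.
#'
#' @param target a [cause_distribution].
#' @param n number of deaths in the replicate.
#' @return named integer vector of per-cause counts.
#' @export
apportion_counts <- function(target, n) {
  stopifnot(n >= 1)
  largest_remainder(unclass(target), n)
}

#' Resample a labelled death pool to a target distribution
#'
#' Draws the apportioned count of deaths per cause, with replacement, from
#' that cause's pool.  Target causes with an empty pool are dropped by
#' [renormalize_over_available()] before apportionment, so the empirical
#' cause composition of the resample equals `apportion_counts()` exactly.
#'
#' @param pool named list: cause id -> character vector of death ids.
#' @param target a [cause_distribution].
#' @param n resample size (defaults to total pool size).
#' @param replace draw with replacement (default TRUE; without-replacement
#'   fails when a cause's quota exceeds its pool).
#' @return character vector of `n` death ids.
#' @export
resample_to_target <- function(pool, target, n = sum(lengths(pool)),
                               replace = TRUE) {
  available <- names(pool)[lengths(pool) > 0L]
  target <- renormalize_over_available(target, available)
  counts <- apportion_counts(target, n)
  counts <- counts[counts > 0L]
  out <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    cz <- names(counts)[i]
    ids <- pool[[cz]]
    if (length(ids) == 0L) {
      hv_stop(sprintf("cause '%s' retained with an empty pool", cz),
              "hierVA_resampling_error")
    }
    if (!replace && counts[i] > length(ids)) {
      hv_stop(sprintf("cause '%s': quota %d exceeds pool size %d without replacement",
                      cz, counts[i], length(ids)), "hierVA_resampling_error")
    }
    out[[i]] <- ids[sample.int(length(ids), counts[i], replace = replace)]
  }
  unlist(out, use.names = FALSE)
}
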