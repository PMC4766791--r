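#' Cause-assignment hierarchies
#'
#' When more than one expert algorithm fires for a death, the primary cause
#' is the fired cause at the earliest rank of a pre-specified hierarchy.  A
#' rank may hold several causes tied at one level (e.g. "neonatal tetanus,
#' congenital malformation"); within-rank ties among fired causes are broken
#' by the listed (left-to-right) order, with a warning.  Deaths firing no
#' algorithm receive the fallback cause (`"unspecified"`).
#'
#' Nine hierarchies from the published literature ship as bundled JSON
#' configs: six neonatal (`arifeen`, `baqui`, `kalter`, `lawn`, `liu`,
#' `compromise`) and three child (`arifeen`, `kalter`, `liu`).  The bundled
#' configs extend the published columns with grouped synonyms (flagged in
#' their `extended` field) so that every cause in the harmonized scoring
#' vocabulary is rankable under every hierarchy; see the package vignette.
#'
#' @param name hierarchy name (free text for user-built hierarchies).
#' @param age_group `"neonate"` or `"child"`.
#' @param ranks list of character vectors: causes at each rank, earliest
#'   first; within-rank order is the tie-break order.
#' @param fallback cause id assigned when no algorithm fires.
#' @return a `hierarchy` object.
#' @export
hierarchy <- function(name, age_group = c("neonate", "child"), ranks,
                      fallback = "unspecified") {
  age_group <- match.arg(age_group)
  stopifnot(is.list(ranks), length(ranks) >= 1L)
  ranks <- lapply(ranks, as.character)
  all_causes <- unlist(ranks)
  if (anyDuplicated(all_causes)) {
    hv_stop(sprintf("cause(s) %s appear at more than one rank",
                    paste(unique(all_causes[duplicated(all_causes)]),
                          collapse = ", ")),
            "hierVA_config_error")
  }
  if (fallback %in% all_causes) {
    hv_stop("fallback cause must not also be ranked", "hierVA_config_error")
  }
  structure(list(name = name, age_group = age_group, ranks = ranks,
                 fallback_cause = fallback),
            class = "hierarchy")
}

#' @export
print.hierarchy <- function(x, ...) {
  cat(sprintf("<hierarchy> '%s' (%s), %d ranks, fallback '%s'\n",
              x$name, x$age_group, length(x$ranks), x$fallback_cause))
  for (i in seq_along(x$ranks)) {
    cat(sprintf("  %2d. %s\n", i, paste(x$ranks[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Load a hierarchy from a bundled name or a JSON file
#'
#' @param name bundled hierarchy name (see [list_hierarchies()]) or a path
#'   to a hierarchy JSON file.
#' @param age_group required for bundled names.
#' @return a [hierarchy] object.
#' @export
load_hierarchy <- function(name, age_group = c("neonate", "child")) {
  path <- if (file.exists(name)) name else {
    age_group <- match.arg(age_group)
    hierva_example("hierarchies", sprintf("%s_%s.json", age_group, name))
  }
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (req in c("name", "age_group", "ranks")) {
    if (is.null(cfg[[req]])) {
      hv_stop(sprintf("hierarchy config missing '%s'", req),
              "hierVA_config_error")
    }
  }
  h <- hierarchy(cfg$name, cfg$age_group,
                 lapply(cfg$ranks, function(r) unlist(r)),
                 fallback = cfg$fallback %||% "unspecified")
  h$label <- cfg$label %||% cfg$name
  h
}

#' List the bundled hierarchies
#'
#' @return data frame with columns `age_group` and `name`.
#' @export
list_hierarchies <- function() {
  files <- list.files(system.file("extdata", "hierarchies", package = "hierVA"),
                      pattern = "[.]json$")
  parts <- strsplit(sub("[.]json$", "", files), "_")
  data.frame(age_group = vapply(parts, `[`, "", 1L),
             name = vapply(parts, function(p) paste(p[-1L], collapse = "_"), ""),
             stringsAsFactors = FALSE)
}

# rank index of each cause; unranked causes get Inf (fallback level)
cause_rank <- function(hierarchy, causes) {
  rk <- rep(Inf, length(causes))
  within <- rep(Inf, length(causes))
  for (i in seq_along(hierarchy$ranks)) {
    hit <- match(causes, hierarchy$ranks[[i]])
    sel <- !is.na(hit)
    rk[sel] <- i
    within[sel] <- hit[sel]
  }
  list(rank = rk, within = within)
}

#' Select the primary cause among fired causes
#'
#' Returns the fired cause at the earliest hierarchy rank.  An empty fired
#' set yields the fallback cause.  Two fired causes tied at one rank are
#' resolved by the within-rank listed order (warning of class
#' `hierVA_tie`); fired causes the hierarchy does not rank fall to the
#' fallback level and are chosen (alphabetically, with a warning) only when
#' no ranked cause fired.
#'
#' @param fired character vector of fired cause ids.
#' @param hierarchy a [hierarchy] object.
#' @return a single cause id.
#' @export
assign_primary_cause <- function(fired, hierarchy) {
  stopifnot(inherits(hierarchy, "hierarchy"))
  fired <- unique(as.character(fired))
  if (length(fired) == 0L) return(hierarchy$fallback_cause)
  pos <- cause_rank(hierarchy, fired)
  if (all(is.infinite(pos$rank))) {
    # no fired cause is ranked: everything maps to the fallback level
    if (length(fired) > 1L) {
      hv_warn(sprintf("hierarchy '%s' ranks none of: %s; using '%s'",
                      hierarchy$name, paste(fired, collapse = ", "),
                      sort(fired)[1L]),
              "hierVA_unranked")
      return(sort(fired)[1L])
    }
    hv_warn(sprintf("hierarchy '%s' does not rank cause '%s'; treated as fallback",
                    hierarchy$name, fired), "hierVA_unranked")
    return(fired)
  }
  best <- min(pos$rank)
  at_best <- which(pos$rank == best)
  if (length(at_best) > 1L) {
    winner <- at_best[which.min(pos$within[at_best])]
    hv_warn(sprintf("tie at rank %d of hierarchy '%s' (%s); choosing '%s' by listed order",
                    best, hierarchy$name,
                    paste(fired[at_best], collapse = ", "), fired[winner]),
            "hierVA_tie")
    return(fired[winner])
  }
  fired[at_best]
}

#' Check that a hierarchy covers a rule set
#'
#' Verifies that every cause a rule set can emit is either ranked by the
#' hierarchy or explicitly acceptable as fallback.
#'
#' @param hierarchy a [hierarchy].
#' @param ruleset a `ruleset` of the same age group.
#' @return invisibly, the character vector of unranked rule causes (empty
#'   when the hierarchy fully covers the rule set).
#' @export
validate_hierarchy <- function(hierarchy, ruleset) {
  stopifnot(inherits(hierarchy, "hierarchy"), inherits(ruleset, "ruleset"))
  if (!identical(hierarchy$age_group, ruleset$age_group)) {
    hv_stop("hierarchy and rule set are for different age groups",
            "hierVA_usage_error")
  }
  unranked <- setdiff(names(ruleset$rules), unlist(hierarchy$ranks))
  if (length(unranked)) {
    hv_warn(sprintf("hierarchy '%s' does not rank rule cause(s): %s (will fall back to '%s')",
                    hierarchy$name, paste(unranked, collapse = ", "),
                    hierarchy$fallback_cause),
            "hierVA_unranked")
  }
  invisible(unranked)
}
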