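#' Reference-standard labels
#'
#' One row per death with its (possibly co-morbid) reference-standard
#' cause(s).  Causes are stored as a pipe-separated string in the `causes`
#' column, e.g. `"preterm_delivery|sepsis"`.
#'
#' @param df data frame with columns `death_id` and `causes`.
#' @param age_group `"neonate"` or `"child"`.
#' @return a `reference_labels` object.
#' @export
reference_labels <- function(df, age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  if (!is.data.frame(df) || !all(c("death_id", "causes") %in% names(df))) {
    hv_stop("reference labels need columns death_id and causes",
            "hierVA_input_error")
  }
  df$death_id <- as.character(df$death_id)
  df$causes <- as.character(df$causes)
  if (anyDuplicated(df$death_id)) {
    hv_stop("duplicate death_id in reference labels", "hierVA_input_error")
  }
  if (any(!nzchar(df$causes) | is.na(df$causes))) {
    hv_stop("every death needs a non-empty reference cause set",
            "hierVA_input_error")
  }
  structure(df[c("death_id", "causes")], age_group = age_group,
            class = c("reference_labels", "data.frame"))
}

#' Read reference-standard labels from CSV
#'
#' Expects columns `death_id` and `causes` (pipe-separated cause set).
#'
#' @inheritParams read_va_records
#' @return a [reference_labels] object.
#' @export
read_reference_labels <- function(path, age_group = c("neonate", "child")) {
  reference_labels(utils::read.csv(path, stringsAsFactors = FALSE),
                   match.arg(age_group))
}

split_causes <- function(x) strsplit(x, "|", fixed = TRUE)

#' Load a cause map
#'
#' A cause map drives reference-standard harmonization and the collapsing
#' of "possible" verbal-autopsy causes before scoring.  JSON schema:
#'
#' ```
#' {
#'   "age_group": "neonate",
#'   "direct":   {"rds": "preterm_delivery", ...},
#'   "comorbid": [
#'     {"pattern": ["preterm_delivery", "birth_asphyxia"], "target": "birth_asphyxia"},
#'     {"pattern": ["preterm_delivery", "sepsis", "birth_asphyxia"],
#'      "proportional": ["sepsis", "birth_asphyxia"]}
#'   ],
#'   "groups":   {"possible_pneumonia": "pneumonia", ...}
#' }
#' ```
#'
#' `direct` renames single reference causes; singletons absent from
#' `direct` map to themselves.  `comorbid` patterns match cause sets
#' exactly (order-free) and either name a single `target` or allocate
#' `"proportional"`ly over two or more targets.  `groups` recodes VA
#' causes to their scoring cause ("possible pneumonia" to pneumonia).
#' Bundled maps: `causemap_neonate.json`, `causemap_child.json`.
#'
#' @param path JSON file path, or the bundled age group name
#'   (`"neonate"`/`"child"`).
#' @return a `cause_map` object.
#' @export
load_cause_map <- function(path) {
  if (path %in% c("neonate", "child")) {
    path <- hierva_example(sprintf("causemap_%s.json", path))
  }
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  comorbid <- lapply(cfg$comorbid %||% list(), function(r) {
    pat <- sort(unlist(r$pattern))
    if (length(pat) < 2L) {
      hv_stop("comorbid pattern needs at least two causes", "hierVA_config_error")
    }
    if (!is.null(r$proportional)) {
      tg <- unlist(r$proportional)
      if (length(tg) < 2L) {
        hv_stop("proportional rule needs at least two targets",
                "hierVA_config_error")
      }
      list(pattern = pat, proportional = tg)
    } else if (!is.null(r$target)) {
      list(pattern = pat, target = r$target)
    } else {
      hv_stop("comorbid rule needs 'target' or 'proportional'",
              "hierVA_config_error")
    }
  })
  pats <- vapply(comorbid, function(r) paste(r$pattern, collapse = "|"), "")
  if (anyDuplicated(pats)) {
    hv_stop("comorbid patterns must be disjoint", "hierVA_config_error")
  }
  structure(list(age_group = cfg$age_group %||% NA_character_,
                 direct = unlist(cfg$direct %||% list()),
                 comorbid = comorbid,
                 groups = unlist(cfg$groups %||% list())),
            class = "cause_map")
}

#' Harmonize co-morbid reference causes to single underlying causes
#'
#' Applies ICD-10-style rules: singleton causes pass through `direct`
#' renaming; exact co-morbid patterns map to their target; proportional
#' patterns are split over their targets in the ratio of deaths already
#' singly assigned to those targets, using deterministic largest-remainder
#' rounding (matched deaths are allocated in input order).  The total death
#' count is conserved.
#'
#' @param labels a [reference_labels] object.
#' @param map a `cause_map` from [load_cause_map()].
#' @return named character vector: `death_id` -> single harmonized cause.
#' @export
harmonize_comorbid <- function(labels, map) {
  stopifnot(inherits(map, "cause_map"))
  sets <- split_causes(labels$causes)
  keys <- vapply(sets, function(s) paste(sort(unique(s)), collapse = "|"), "")
  out <- rep(NA_character_, nrow(labels))
  names(out) <- labels$death_id

  single <- lengths(sets) == 1L
  sv <- unlist(lapply(sets[single], `[`, 1L))
  renamed <- ifelse(sv %in% names(map$direct), unname(map$direct[sv]), sv)
  out[single] <- renamed

  pat_keys <- vapply(map$comorbid, function(r) paste(r$pattern, collapse = "|"), "")
  pending <- list()  # proportional rules deferred until singles are counted
  for (i in which(!single)) {
    j <- match(keys[i], pat_keys)
    if (is.na(j)) {
      hv_stop(sprintf("no harmonization rule matches cause set {%s} (death %s)",
                      gsub("[|]", ", ", keys[i]), labels$death_id[i]),
              "hierVA_mapping_error")
    }
    rule <- map$comorbid[[j]]
    if (!is.null(rule$target)) {
      out[i] <- rule$target
    } else {
      pending[[keys[i]]] <- c(pending[[keys[i]]], i)
    }
  }

  if (length(pending)) {
    assigned <- table(out[!is.na(out)])
    for (k in names(pending)) {
      rule <- map$comorbid[[match(k, pat_keys)]]
      idx <- pending[[k]]
      shares <- vapply(rule$proportional,
                       function(t) as.numeric(assigned[t] %||% 0) , 0)
      shares[is.na(shares)] <- 0
      names(shares) <- rule$proportional
      if (sum(shares) == 0) {
        hv_stop(sprintf("proportional rule for {%s}: no deaths singly assigned to any of %s",
                        gsub("[|]", ", ", k),
                        paste(rule$proportional, collapse = ", ")),
                "hierVA_allocation_error")
      }
      counts <- largest_remainder(shares, length(idx))
      out[idx] <- rep(names(counts), counts)
    }
  }
  out
}

#' Collapse "possible" causes into their scoring causes
#'
#' Recodes grouped verbal-autopsy causes (e.g. possible pneumonia) to the
#' definite cause they are scored with; ungrouped causes pass through
#' unchanged.  Idempotent; death count conserved.
#'
#' @param assignments named character vector `death_id` -> cause id.
#' @param map a `cause_map`.
#' @return named character vector of the same length.
#' @export
collapse_groups <- function(assignments, map) {
  stopifnot(inherits(map, "cause_map"))
  if (length(map$groups) == 0L) return(assignments)
  hit <- assignments %in% names(map$groups)
  assignments[hit] <- unname(map$groups[assignments[hit]])
  assignments
}
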