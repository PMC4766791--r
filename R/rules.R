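#' @title Verbal autopsy records
#'
#' @description A `va_records` object is a data frame with one row per death:
#' a `death_id` column, one column per binary symptom holding responses
#' `"yes"`, `"no"`, `"dont_know"` or `NA` (missing), and optional numeric
#' symptom columns (durations in days, counts).  The age group
#' (`"neonate"` for 0-27 days, `"child"` for 1-59 months) is carried as an
#' attribute: expert algorithms and hierarchies are age-group specific.
#'
#' @param df data frame with a `death_id` column plus symptom columns.
#' @param age_group `"neonate"` or `"child"`.
#' @return a `va_records` object (a validated data frame).
#' @export
va_records <- function(df, age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  if (!is.data.frame(df) || !"death_id" %in% names(df)) {
    hv_stop("records must be a data frame with a 'death_id' column",
            "hierVA_input_error")
  }
  df$death_id <- as.character(df$death_id)
  if (anyDuplicated(df$death_id)) {
    hv_stop("duplicate death_id in records", "hierVA_input_error")
  }
  ok <- c("yes", "no", "dont_know")
  for (col in setdiff(names(df), "death_id")) {
    if (is.numeric(df[[col]])) {
      if (any(df[[col]] < 0, na.rm = TRUE)) {
        hv_stop(sprintf("numeric symptom '%s' has negative values", col),
                "hierVA_input_error")
      }
      next
    }
    v <- as.character(df[[col]])
    bad <- !(v %in% ok | is.na(v))
    if (any(bad)) {
      hv_stop(sprintf("symptom '%s' has responses outside {yes,no,dont_know,NA}: %s",
                      col, paste(unique(v[bad]), collapse = ", ")),
              "hierVA_input_error")
    }
    df[[col]] <- v
  }
  structure(df, age_group = age_group,
            class = c("va_records", "data.frame"))
}

#' @export
print.va_records <- function(x, ...) {
  cat(sprintf("<va_records> %d deaths, age group '%s', %d symptom columns\n",
              nrow(x), attr(x, "age_group"), ncol(x) - 1L))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read verbal autopsy records from CSV
#'
#' The CSV has one row per death, first column `death_id`, one column per
#' symptom.  Binary responses are coded `Y`/`N`/`DK`/blank (blank = missing);
#' numeric columns are plain numbers.  An optional column-mapping JSON file
#' (`{"questionnaire header": "symptom_id", ...}`) renames arbitrary
#' questionnaire headers to internal symptom ids before validation.
#'
#' @param path CSV file path.
#' @param age_group `"neonate"` or `"child"`.
#' @param mapping optional path to a JSON column-mapping file.
#' @return a [va_records] object.
#' @export
read_va_records <- function(path, age_group = c("neonate", "child"),
                            mapping = NULL) {
  age_group <- match.arg(age_group)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = "")
  if (!is.null(mapping)) {
    mp <- jsonlite::read_json(mapping, simplifyVector = TRUE)
    hit <- names(df) %in% names(mp)
    names(df)[hit] <- unlist(mp[names(df)[hit]])
  }
  code <- c(Y = "yes", N = "no", DK = "dont_know",
            yes = "yes", no = "no", dont_know = "dont_know")
  for (col in setdiff(names(df), "death_id")) {
    if (is.numeric(df[[col]])) next
    v <- toupper(trimws(as.character(df[[col]])))
    v[v == ""] <- NA
    mapped <- unname(code[v])
    bad <- !is.na(v) & is.na(mapped)
    if (any(bad)) {
      hv_stop(sprintf("column '%s': unrecognised response code(s) %s",
                      col, paste(unique(v[bad]), collapse = ", ")),
              "hierVA_input_error")
    }
    df[[col]] <- mapped
  }
  va_records(df, age_group)
}

#' Write verbal autopsy records to CSV
#'
#' Inverse of [read_va_records()]: binary responses are written as
#' `Y`/`N`/`DK` with blanks for missing.
#'
#' @param records a [va_records] object.
#' @param path output CSV path.
#' @export
write_va_records <- function(records, path) {
  df <- as.data.frame(records)
  code <- c(yes = "Y", no = "N", dont_know = "DK")
  for (col in setdiff(names(df), "death_id")) {
    if (is.numeric(df[[col]])) next
    df[[col]] <- unname(code[df[[col]]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Rule sets: expert algorithms as boolean predicates over symptoms
## ---------------------------------------------------------------------------

# Predicate grammar (JSON):
#   atom      {"symptom": id, "is": "yes"|"no"}            binary symptom
#             {"symptom": id, "op": ">="|"<=", "value": x} numeric symptom
#             either may carry "dk": "false"|"as_no" to override the rule
#             set's dont-know policy for that atom
#   combinator {"all": [p, ...]}  {"any": [p, ...]}  {"not": p}
# Missing and dont_know responses make an atom FALSE under the default
# policy "false"; under "as_no" they satisfy {"is": "no"} atoms.

validate_predicate <- function(pred, symptoms, where) {
  if (!is.list(pred)) {
    hv_stop(sprintf("%s: predicate must be an object", where),
            "hierVA_parse_error")
  }
  keys <- names(pred)
  if ("all" %in% keys || "any" %in% keys) {
    op <- intersect(c("all", "any"), keys)
    if (length(op) != 1L || length(setdiff(keys, op)) > 0L) {
      hv_stop(sprintf("%s: combinator must be exactly one of all/any/not", where),
              "hierVA_parse_error")
    }
    kids <- pred[[op]]
    if (!is.list(kids) || length(kids) == 0L) {
      hv_stop(sprintf("%s: '%s' needs a non-empty list of predicates", where, op),
              "hierVA_parse_error")
    }
    for (i in seq_along(kids)) {
      validate_predicate(kids[[i]], symptoms, sprintf("%s/%s[%d]", where, op, i))
    }
    return(invisible(TRUE))
  }
  if ("not" %in% keys) {
    if (length(setdiff(keys, "not")) > 0L) {
      hv_stop(sprintf("%s: 'not' takes a single predicate", where),
              "hierVA_parse_error")
    }
    validate_predicate(pred[["not"]], symptoms, paste0(where, "/not"))
    return(invisible(TRUE))
  }
  # atom
  sid <- pred[["symptom"]]
  if (is.null(sid) || !is.character(sid) || length(sid) != 1L) {
    hv_stop(sprintf("%s: atom needs a 'symptom' id", where), "hierVA_parse_error")
  }
  if (!sid %in% symptoms$symptom_id) {
    hv_stop(sprintf("%s: undeclared symptom '%s'", where, sid),
            "hierVA_parse_error")
  }
  type <- symptoms$type[symptoms$symptom_id == sid]
  extra <- setdiff(keys, c("symptom", "is", "op", "value", "dk"))
  if (length(extra)) {
    hv_stop(sprintf("%s: unknown atom field(s) %s", where,
                    paste(extra, collapse = ", ")), "hierVA_parse_error")
  }
  if (!is.null(pred[["dk"]]) && !pred[["dk"]] %in% c("false", "as_no")) {
    hv_stop(sprintf("%s: dk policy must be 'false' or 'as_no'", where),
            "hierVA_parse_error")
  }
  if (type == "binary") {
    if (is.null(pred[["is"]]) || !pred[["is"]] %in% c("yes", "no")) {
      hv_stop(sprintf("%s: binary atom on '%s' needs is: yes|no", where, sid),
              "hierVA_parse_error")
    }
    if (!is.null(pred[["op"]]) || !is.null(pred[["value"]])) {
      hv_stop(sprintf("%s: binary atom on '%s' cannot carry op/value", where, sid),
              "hierVA_parse_error")
    }
  } else {
    if (is.null(pred[["op"]]) || !pred[["op"]] %in% c(">=", "<=")) {
      hv_stop(sprintf("%s: numeric atom on '%s' needs op: >= or <=", where, sid),
              "hierVA_parse_error")
    }
    if (is.null(pred[["value"]]) || !is.numeric(pred[["value"]])) {
      hv_stop(sprintf("%s: numeric atom on '%s' needs a numeric 'value'",
                      where, sid), "hierVA_parse_error")
    }
  }
  invisible(TRUE)
}

#' Parse an expert-algorithm rule set
#'
#' A rule set declares a symptom dictionary and an ordered list of cause
#' rules.  Each rule is a boolean predicate over symptom atoms
#' (`symptom == yes`, `symptom == no`, numeric `>=`/`<=` threshold) combined
#' with `all`/`any`/`not`.  The JSON schema:
#'
#' ```
#' {
#'   "age_group": "neonate",
#'   "dk_policy": "false",           # or "as_no"
#'   "symptoms": {
#'     "fed_normally": {"type": "binary", "label": "ever fed normally"},
#'     "illness_days": {"type": "numeric", "unit": "days"}
#'   },
#'   "rules": [
#'     {"cause": "sepsis",
#'      "predicate": {"all": [{"symptom": "fed_normally", "is": "no"},
#'                            {"symptom": "illness_days", "op": ">=", "value": 3}]}}
#'   ]
#' }
#' ```
#'
#' The default dont-know policy `"false"` makes any atom that references a
#' missing or dont-know response evaluate false; `"as_no"` lets such
#' responses satisfy `is: no` atoms.  A per-atom `"dk"` field overrides the
#' rule-set policy.
#'
#' @param text JSON text, or a path to a JSON file.
#' @return a `ruleset` object.
#' @export
parse_ruleset <- function(text) {
  if (length(text) == 1L && !grepl("[{]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  cfg <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) {
                    hv_stop(paste("malformed JSON:", conditionMessage(e)),
                            "hierVA_parse_error")
                  })
  for (req in c("age_group", "symptoms", "rules")) {
    if (is.null(cfg[[req]])) {
      hv_stop(sprintf("rule set missing required field '%s'", req),
              "hierVA_parse_error")
    }
  }
  if (!cfg$age_group %in% c("neonate", "child")) {
    hv_stop("age_group must be 'neonate' or 'child'", "hierVA_parse_error")
  }
  dk <- cfg$dk_policy %||% "false"
  if (!dk %in% c("false", "as_no")) {
    hv_stop("dk_policy must be 'false' or 'as_no'", "hierVA_parse_error")
  }
  sym <- cfg$symptoms
  if (length(sym) == 0L || is.null(names(sym)) || anyDuplicated(names(sym))) {
    hv_stop("symptoms must be a named map with unique ids", "hierVA_parse_error")
  }
  symptoms <- data.frame(
    symptom_id = names(sym),
    type = vapply(sym, function(s) s$type %||% "binary", ""),
    unit = vapply(sym, function(s) s$unit %||% NA_character_, ""),
    label = vapply(sym, function(s) s$label %||% NA_character_, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  bad <- !symptoms$type %in% c("binary", "numeric")
  if (any(bad)) {
    hv_stop(sprintf("symptom '%s': type must be binary or numeric",
                    symptoms$symptom_id[bad][1]), "hierVA_parse_error")
  }
  rules <- list()
  for (i in seq_along(cfg$rules)) {
    r <- cfg$rules[[i]]
    if (is.null(r$cause) || is.null(r$predicate)) {
      hv_stop(sprintf("rule %d: needs 'cause' and 'predicate'", i),
              "hierVA_parse_error")
    }
    if (r$cause %in% names(rules)) {
      hv_stop(sprintf("duplicate cause_id '%s'", r$cause), "hierVA_parse_error")
    }
    validate_predicate(r$predicate, symptoms, sprintf("rule '%s'", r$cause))
    rules[[r$cause]] <- r$predicate
  }
  structure(list(age_group = cfg$age_group, dk_policy = dk,
                 symptoms = symptoms, rules = rules),
            class = "ruleset")
}

#' Serialize a rule set back to JSON
#'
#' `parse_ruleset(serialize_ruleset(rs))` yields an object equal to `rs`.
#'
#' @param ruleset a `ruleset` object.
#' @return a JSON string.
#' @export
serialize_ruleset <- function(ruleset) {
  stopifnot(inherits(ruleset, "ruleset"))
  sym <- ruleset$symptoms
  symlist <- lapply(seq_len(nrow(sym)), function(i) {
    s <- list(type = sym$type[i])
    if (!is.na(sym$unit[i])) s$unit <- sym$unit[i]
    if (!is.na(sym$label[i])) s$label <- sym$label[i]
    s
  })
  names(symlist) <- sym$symptom_id
  out <- list(age_group = ruleset$age_group,
              dk_policy = ruleset$dk_policy,
              symptoms = symlist,
              rules = lapply(names(ruleset$rules), function(cz) {
                list(cause = cz, predicate = ruleset$rules[[cz]])
              }))
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("<ruleset> age group '%s', %d rules, %d symptoms, dk policy '%s'\n",
              x$age_group, length(x$rules), nrow(x$symptoms), x$dk_policy))
  cat("causes:", paste(names(x$rules), collapse = ", "), "\n")
  invisible(x)
}

# Evaluate one predicate against all records at once; returns a logical
# vector with one element per row.  `complete = TRUE` treats the record as
# fully observed (used by the symptom-model solver, where there is no
# missingness).
eval_predicate <- function(pred, records, ruleset, complete = FALSE) {
  n <- nrow(records)
  keys <- names(pred)
  if ("all" %in% keys) {
    out <- rep(TRUE, n)
    for (p in pred$all) out <- out & eval_predicate(p, records, ruleset, complete)
    return(out)
  }
  if ("any" %in% keys) {
    out <- rep(FALSE, n)
    for (p in pred$any) out <- out | eval_predicate(p, records, ruleset, complete)
    return(out)
  }
  if ("not" %in% keys) {
    return(!eval_predicate(pred$not, records, ruleset, complete))
  }
  sid <- pred$symptom
  v <- if (sid %in% names(records)) records[[sid]] else rep(NA, n)
  if (!is.null(pred$is)) {
    v <- as.character(v)
    if (pred$is == "yes") {
      out <- !is.na(v) & v == "yes"
    } else {
      dk <- pred$dk %||% ruleset$dk_policy
      if (dk == "as_no" && !complete) {
        out <- is.na(v) | v %in% c("no", "dont_know")
      } else {
        out <- !is.na(v) & v == "no"
      }
    }
    return(out)
  }
  v <- suppressWarnings(as.numeric(v))
  out <- if (pred$op == ">=") v >= pred$value else v <= pred$value
  out[is.na(out)] <- FALSE
  out
}

#' Evaluate every expert algorithm on a set of records
#'
#' @param records a [va_records] object (or plain data frame in the same
#'   layout).
#' @param ruleset a `ruleset` from [parse_ruleset()].
#' @return a logical matrix, one row per death (rownames = `death_id`), one
#'   column per cause; `TRUE` where the cause's predicate fires.
#' @export
evaluate_records <- function(records, ruleset) {
  stopifnot(inherits(ruleset, "ruleset"))
  if (inherits(records, "va_records") &&
      !identical(attr(records, "age_group"), ruleset$age_group)) {
    hv_stop(sprintf("age-group mismatch: records are '%s', rule set is '%s'",
                    attr(records, "age_group"), ruleset$age_group),
            "hierVA_usage_error")
  }
  fired <- vapply(ruleset$rules, eval_predicate, logical(nrow(records)),
                  records = records, ruleset = ruleset)
  if (nrow(records) == 1L) fired <- matrix(fired, nrow = 1L,
                                           dimnames = list(NULL, names(ruleset$rules)))
  rownames(fired) <- records$death_id
  fired
}

#' Causes fired by a single record
#'
#' Returns every cause whose predicate is true for the record; the verbal
#' autopsy analogue of "all contributing causes".  Deterministic: identical
#' responses always yield identical causes.
#'
#' @param record a one-row [va_records] object (or data frame).
#' @param ruleset a `ruleset`.
#' @return character vector of fired cause ids (possibly empty).
#' @export
evaluate_record <- function(record, ruleset) {
  if (nrow(record) != 1L) {
    hv_stop("evaluate_record expects exactly one record; see evaluate_records",
            "hierVA_usage_error")
  }
  fired <- evaluate_records(record, ruleset)
  colnames(fired)[fired[1L, ]]
}

#' Classify a data set of verbal autopsies
#'
#' Runs every expert algorithm on every record and selects the primary
#' cause per death through the hierarchy.
#'
#' @param records a [va_records] object.
#' @param ruleset a `ruleset`.
#' @param hierarchy a [hierarchy] object of the same age group.
#' @return named character vector: `death_id` -> primary cause id.
#' @export
classify_dataset <- function(records, ruleset, hierarchy) {
  if (anyDuplicated(records$death_id)) {
    hv_stop("duplicate death_id in records", "hierVA_input_error")
  }
  if (!identical(ruleset$age_group, hierarchy$age_group)) {
    hv_stop("rule set and hierarchy are for different age groups",
            "hierVA_usage_error")
  }
  fired <- evaluate_records(records, ruleset)
  out <- vapply(seq_len(nrow(fired)), function(i) {
    assign_primary_cause(colnames(fired)[fired[i, ]], hierarchy)
  }, "")
  names(out) <- records$death_id
  out
}
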