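# Validation pipeline: classify -> harmonize -> resample x R -> score -> summarize

# metrics for one resampled replicate, given precomputed truth and
# predictions for every pooled death
replicate_metrics <- function(true_map, pred_map, ids, fallback = "unspecified",
                              unspecified = c("class", "drop")) {
  unspecified <- match.arg(unspecified)
  true <- unname(true_map[ids])
  pred <- unname(pred_map[ids])
  cause_list <- sort(unique(c(true, pred)))
  true_csmf <- csmf_from_labels(stats::setNames(true, ids), cause_list)
  pred_csmf <- csmf_from_labels(stats::setNames(pred, ids), cause_list)
  if (unspecified == "drop" && fallback %in% pred) {
    keep <- pred != fallback
    cm <- confusion_matrix(true[keep], pred[keep],
                           sort(unique(c(true[keep], pred[keep]))))
  } else {
    cm <- confusion_matrix(true, pred, cause_list)
  }
  list(csmf_accuracy = csmf_accuracy(pred_csmf, true_csmf),
       kappa = cohens_kappa(cm),
       ccc = chance_corrected_concordance(cm),
       unclassified_fraction = mean(pred == fallback),
       abs_diff = csmf_abs_diff(pred_csmf, true_csmf))
}

#' Run a single validation replicate
#'
#' One pass of the validation experiment: harmonize the reference labels,
#' draw a target cause distribution for the scenario, resample the
#' labelled pool to match it, classify the resampled verbal autopsies
#' through the rule set and hierarchy, collapse "possible" causes, and
#' compute all four agreement metrics.  Uses the current RNG state; wrap in
#' `set.seed()` for reproducibility.
#'
#' @param records a [va_records] object covering the labelled deaths.
#' @param labels a [reference_labels] object.
#' @param ruleset a `ruleset`.
#' @param hierarchy a [hierarchy].
#' @param scenario a [scenario_spec].
#' @param table a `country_csmf_table` (country scenarios).
#' @param n replicate size; defaults to the pool size.
#' @param cause_map a `cause_map` (defaults to the bundled map for the
#'   labels' age group).
#' @param unspecified `"class"` scores unclassified deaths as an
#'   "unspecified" category in kappa; `"drop"` excludes them from the
#'   individual-level confusion matrix.
#' @return a list: `scenario`, `hierarchy`, the four scalar metrics, and
#'   `per_cause_abs_diff`.
#' @export
run_replicate <- function(records, labels, ruleset, hierarchy, scenario,
                          table = NULL, n = NULL,
                          cause_map = load_cause_map(labels_age_group(labels)),
                          unspecified = "class") {
  if (!setequal(records$death_id, labels$death_id)) {
    hv_stop("records and labels must cover the same death_ids",
            "hierVA_usage_error")
  }
  true_map <- harmonize_comorbid(labels, cause_map)
  pred_map <- collapse_groups(classify_dataset(records, ruleset, hierarchy),
                              cause_map)
  pool <- split(names(true_map), unname(true_map))
  if (is.null(n)) n <- length(true_map)
  target <- draw_target_csmf(scenario, table, causes = names(pool))
  ids <- resample_to_target(pool, target, n)
  m <- replicate_metrics(true_map, pred_map, ids,
                         fallback = hierarchy$fallback_cause,
                         unspecified = unspecified)
  list(scenario = scenario$name, hierarchy = hierarchy$name,
       csmf_accuracy = m$csmf_accuracy, kappa = m$kappa, ccc = m$ccc,
       unclassified_fraction = m$unclassified_fraction,
       per_cause_abs_diff = m$abs_diff)
}

#' Run the replicated validation experiment
#'
#' For every scenario, draws `replicates` target cause distributions and
#' resamples of the labelled pool; each resample is shared across all
#' hierarchies (paired comparison: the algorithms and the deaths are held
#' constant while the hierarchy varies), and the four agreement metrics
#' are computed per hierarchy.  Each (scenario, replicate) cell gets an
#' independent RNG seed derived from `seed`, so results do not depend on
#' evaluation order.
#'
#' @inheritParams run_replicate
#' @param hierarchies a list of [hierarchy] objects (or names resolvable by
#'   [load_hierarchy()] for the labels' age group).
#' @param scenarios character vector of scenario names, or a list of
#'   [scenario_spec] objects.
#' @param replicates number of replicates per scenario (the full experiment
#'   uses 1000).
#' @param seed master seed.
#' @return a `va_validation` object: a long data frame `replicates` with
#'   columns `scenario`, `hierarchy`, `replicate`, `metric`, `cause`
#'   (`NA` for overall metrics), `value`, plus bookkeeping fields.
#' @export
run_validation <- function(records, labels, ruleset, hierarchies,
                           scenarios = c("high_u5mr_malaria",
                                         "high_u5mr_no_malaria",
                                         "moderate_u5mr", "general"),
                           table = NULL, n = NULL,
                           cause_map = load_cause_map(labels_age_group(labels)),
                           replicates = 1000L, seed = 1L,
                           unspecified = "class") {
  age <- labels_age_group(labels)
  if (is.character(hierarchies)) {
    hierarchies <- lapply(hierarchies, load_hierarchy, age_group = age)
  }
  if (is.character(scenarios)) scenarios <- lapply(scenarios, scenario_spec)
  if (!setequal(records$death_id, labels$death_id)) {
    hv_stop("records and labels must cover the same death_ids",
            "hierVA_usage_error")
  }
  stopifnot(replicates >= 1)

  true_map <- harmonize_comorbid(labels, cause_map)
  pool <- split(names(true_map), unname(true_map))
  if (is.null(n)) n <- length(true_map)

  # classify the full pool once per hierarchy; replicates only resample
  nwarn <- 0L
  pred_maps <- lapply(hierarchies, function(h) {
    withCallingHandlers(
      collapse_groups(classify_dataset(records, ruleset, h), cause_map),
      hierVA_tie = function(w) { nwarn <<- nwarn + 1L
                                 invokeRestart("muffleWarning") },
      hierVA_unranked = function(w) { nwarn <<- nwarn + 1L
                                      invokeRestart("muffleWarning") })
  })
  names(pred_maps) <- vapply(hierarchies, `[[`, "", "name")

  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             replicates * length(scenarios)),
                  nrow = replicates)
  rows <- vector("list", length(scenarios) * replicates * length(hierarchies))
  k <- 0L
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (r in seq_len(replicates)) {
      set.seed(seeds[r, si])
      target <- draw_target_csmf(sc, table, causes = names(pool))
      ids <- resample_to_target(pool, target, n)
      for (hi in seq_along(hierarchies)) {
        h <- hierarchies[[hi]]
        m <- replicate_metrics(true_map, pred_maps[[hi]], ids,
                               fallback = h$fallback_cause,
                               unspecified = unspecified)
        k <- k + 1L
        rows[[k]] <- data.frame(
          scenario = sc$name, hierarchy = h$name, replicate = r,
          metric = c("csmf_accuracy", "kappa", "ccc",
                     "unclassified_fraction",
                     rep("csmf_abs_diff", length(m$abs_diff))),
          cause = c(NA, NA, NA, NA, names(m$abs_diff)),
          value = c(m$csmf_accuracy, m$kappa, m$ccc,
                    m$unclassified_fraction, unname(m$abs_diff)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nwarn > 0L) {
    message(sprintf("run_validation: %d tie/unranked-cause event(s) during classification",
                    nwarn))
  }
  structure(list(replicates = do.call(rbind, rows),
                 n = n, seed = seed, age_group = age),
            class = "va_validation")
}

#' Summarize validation replicates
#'
#' Median and range per (scenario, hierarchy, metric) and, for the
#' per-cause absolute CSMF differences, per cause.  The range is the
#' min-max over replicates by default; `"central95"` reports the
#' 2.5th-97.5th percentile interval instead.
#'
#' @param results a `va_validation` object, or its long `replicates` data
#'   frame.
#' @param range `"minmax"` or `"central95"`.
#' @return data frame with columns `scenario`, `hierarchy`, `metric`,
#'   `cause`, `median`, `range_low`, `range_high`.
#' @export
summarize_validation <- function(results, range = c("minmax", "central95")) {
  range <- match.arg(range)
  df <- if (inherits(results, "va_validation")) results$replicates else results
  if (is.null(df) || nrow(df) == 0L) {
    hv_stop("no replicate results to summarize", "hierVA_usage_error")
  }
  key <- interaction(df$scenario, df$hierarchy, df$metric,
                     ifelse(is.na(df$cause), "", df$cause), drop = TRUE)
  parts <- split(df, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    v <- p$value
    lim <- if (range == "minmax") c(min(v), max(v))
           else unname(stats::quantile(v, c(0.025, 0.975), type = 7))
    data.frame(scenario = p$scenario[1], hierarchy = p$hierarchy[1],
               metric = p$metric[1], cause = p$cause[1],
               median = stats::median(v),
               range_low = lim[1], range_high = lim[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$scenario, out$hierarchy, out$metric,
            ifelse(is.na(out$cause), "", out$cause)), ]
}

#' @export
print.va_validation <- function(x, ...) {
  cat(sprintf("<va_validation> %s, n = %d per replicate, seed = %d\n",
              x$age_group, x$n, x$seed))
  s <- summarize_validation(x)
  ov <- s[is.na(s$cause) & s$metric == "csmf_accuracy", ]
  cat("CSMF accuracy, median (range):\n")
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-22s %-12s %.2f (%.2f-%.2f)\n", ov$scenario[i],
                ov$hierarchy[i], ov$median[i], ov$range_low[i],
                ov$range_high[i]))
  }
  invisible(x)
}

#' Write validation outputs to a directory
#'
#' Writes the tidy per-replicate CSV (`replicates.csv`), the summary CSV
#' (`summary.csv`) and a JSON copy of the summary (`summary.json`).
#'
#' @param results a `va_validation` object.
#' @param dir output directory (created if needed).
#' @param range passed to [summarize_validation()].
#' @return invisibly, the directory path.
#' @export
write_validation <- function(results, dir, range = "minmax") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  s <- summarize_validation(results, range)
  utils::write.csv(s, file.path(dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(s, file.path(dir, "summary.json"), dataframe = "rows",
                       na = "null", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
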