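#' Illustrative expert-algorithm rule sets
#'
#' Builds a self-contained rule set for an age group whose causes match the
#' harmonized validation vocabulary (six neonatal causes: prematurity,
#' birth asphyxia, congenital malformation, meningitis, pneumonia, sepsis;
#' nine child causes: AIDS, diarrhea, measles, meningitis/encephalitis,
#' malaria, pneumonia, injury, other infectious, non-infectious).  Each
#' cause gets a disjoint two-symptom signature (`<cause>_a = yes AND
#' <cause>_b = yes`).  These are documented placeholders for published
#' expert algorithms, which are field-editable configuration, not code:
#' real analyses should load their own rule-set JSON via [parse_ruleset()].
#'
#' @param age_group `"neonate"` or `"child"`.
#' @return a `ruleset` object.
#' @export
demo_ruleset <- function(age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  causes <- if (age_group == "neonate") {
    c("preterm_delivery", "birth_asphyxia", "congenital_malformation",
      "meningitis", "pneumonia", "sepsis")
  } else {
    c("aids", "diarrhea", "measles", "meningitis", "malaria", "pneumonia",
      "injury", "other_infectious", "non_infectious")
  }
  sym <- list()
  rules <- list()
  for (cz in causes) {
    a <- paste0(cz, "_a"); b <- paste0(cz, "_b")
    sym[[a]] <- list(type = "binary", label = paste("sign A of", cz))
    sym[[b]] <- list(type = "binary", label = paste("sign B of", cz))
    rules[[length(rules) + 1L]] <- list(
      cause = cz,
      predicate = list(all = list(list(symptom = a, is = "yes"),
                                  list(symptom = b, is = "yes"))))
  }
  parse_ruleset(jsonlite::toJSON(list(age_group = age_group,
                                      dk_policy = "false",
                                      symptoms = sym, rules = rules),
                                 auto_unbox = TRUE))
}

#' Generator configuration for synthetic reference deaths
#'
#' @param age_group `"neonate"` or `"child"`.
#' @param csmf a [cause_distribution] over single causes.
#' @param comorbid_rates named list: pipe-separated cause set -> probability
#'   that a death drawn with one of the member causes becomes that
#'   co-morbid set (e.g.
#'   `list("preterm_delivery|sepsis" = 0.05)`).
#' @param n number of deaths.
#' @return a `generator_config` object.
#' @export
generator_config <- function(age_group = c("neonate", "child"), csmf,
                             comorbid_rates = list(), n = 1000L) {
  age_group <- match.arg(age_group)
  csmf <- cause_distribution(csmf)
  for (key in names(comorbid_rates)) {
    members <- strsplit(key, "|", fixed = TRUE)[[1L]]
    if (!all(members %in% names(csmf))) {
      hv_stop(sprintf("comorbid set {%s} names cause(s) absent from the CSMF",
                      gsub("[|]", ", ", key)),
              "hierVA_config_error")
    }
    stopifnot(comorbid_rates[[key]] >= 0, comorbid_rates[[key]] <= 1)
  }
  structure(list(age_group = age_group, csmf = csmf,
                 comorbid_rates = comorbid_rates, n = as.integer(n)),
            class = "generator_config")
}

#' Generate reference-standard labelled deaths
#'
#' Each death draws a single cause from the configured CSMF; a death whose
#' cause belongs to one or more co-morbid sets is then upgraded to a
#' co-morbid label with the configured per-set probabilities (at most one
#' set per death).  Reproducible under `set.seed()`.
#'
#' @param config a [generator_config].
#' @return a [reference_labels] object with `config$n` rows.
#' @export
generate_reference_deaths <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  single <- sample(names(config$csmf), n, replace = TRUE,
                   prob = unclass(config$csmf))
  causes <- single
  sets <- lapply(names(config$comorbid_rates),
                 function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  if (length(sets)) {
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      applicable <- which(vapply(sets, function(s) single[i] %in% s, TRUE))
      if (!length(applicable)) next
      p <- cumsum(unlist(config$comorbid_rates[applicable]))
      if (p[length(p)] > 1) {
        hv_stop("comorbid rates applicable to one cause exceed 1",
                "hierVA_config_error")
      }
      hit <- which(u[i] <= p)
      if (length(hit)) {
        causes[i] <- paste(sets[[applicable[hit[1L]]]], collapse = "|")
      }
    }
  }
  reference_labels(data.frame(death_id = sprintf("d%05d", seq_len(n)),
                              causes = causes, stringsAsFactors = FALSE),
                   config$age_group)
}

# find a complete assignment of responses satisfying a predicate, by
# enumeration over the symptoms it references (binary: yes/no; numeric:
# candidate values induced by the thresholds)
predicate_symptoms <- function(pred) {
  keys <- names(pred)
  if ("all" %in% keys) return(unique(unlist(lapply(pred$all, predicate_symptoms))))
  if ("any" %in% keys) return(unique(unlist(lapply(pred$any, predicate_symptoms))))
  if ("not" %in% keys) return(predicate_symptoms(pred$not))
  pred$symptom
}

predicate_thresholds <- function(pred, sid) {
  keys <- names(pred)
  if ("all" %in% keys) return(unlist(lapply(pred$all, predicate_thresholds, sid = sid)))
  if ("any" %in% keys) return(unlist(lapply(pred$any, predicate_thresholds, sid = sid)))
  if ("not" %in% keys) return(predicate_thresholds(pred$not, sid))
  if (identical(pred$symptom, sid) && !is.null(pred$value)) pred$value else NULL
}

satisfying_assignment <- function(pred, ruleset, cause) {
  sids <- predicate_symptoms(pred)
  domains <- lapply(sids, function(s) {
    type <- ruleset$symptoms$type[ruleset$symptoms$symptom_id == s]
    if (type == "binary") c("yes", "no")
    else {
      th <- predicate_thresholds(pred, s)
      sort(unique(pmax(0, c(0, th, th + 1, th - 1))))
    }
  })
  names(domains) <- sids
  combos <- prod(lengths(domains))
  if (combos > 2e5) {
    hv_stop(sprintf("predicate for '%s' references too many symptoms to solve",
                    cause), "hierVA_model_error")
  }
  grid <- expand.grid(domains, stringsAsFactors = FALSE)
  ok <- eval_predicate(pred, grid, ruleset, complete = TRUE)
  if (!any(ok)) {
    hv_stop(sprintf("rule for cause '%s' is unsatisfiable", cause),
            "hierVA_model_error")
  }
  as.list(grid[which(ok)[1L], , drop = FALSE])
}

#' Build a symptom model from a rule set
#'
#' Precomputes, for every cause, a satisfying assignment of its predicate
#' (the cause's symptom *signature*) and stores it with the generation
#' probabilities: `sensitivity` (a true-cause death satisfies its own
#' rule), `specificity` (a death does **not** satisfy a foreign cause's
#' rule) and `background` (an unrelated binary symptom is "yes").  Because
#' signatures are derived from the same rule set the classifier evaluates,
#' generator and classifier share semantics by construction.
#'
#' @param ruleset a `ruleset`.
#' @param sensitivity,specificity,background probabilities in \[0, 1\].
#' @return a `symptom_model` object.
#' @export
build_symptom_model <- function(ruleset, sensitivity = 0.8,
                                specificity = 0.95, background = 0.02) {
  stopifnot(inherits(ruleset, "ruleset"),
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            background >= 0, background <= 1)
  signatures <- lapply(names(ruleset$rules), function(cz) {
    satisfying_assignment(ruleset$rules[[cz]], ruleset, cz)
  })
  names(signatures) <- names(ruleset$rules)
  structure(list(ruleset = ruleset, signatures = signatures,
                 sensitivity = sensitivity, specificity = specificity,
                 background = background),
            class = "symptom_model")
}

#' Generate synthetic verbal autopsy records
#'
#' For each labelled death: with probability `sensitivity` the record is
#' given the (union of the) true cause(s)' signature(s); each foreign
#' cause's signature is applied with probability `1 - specificity`
#' (per-rule leakage, so specificity has a direct confusion-matrix
#' interpretation); every remaining binary symptom is "yes" with the
#' background rate.  Reproducible under `set.seed()`.
#'
#' @param labels a [reference_labels] object.
#' @param model a [build_symptom_model()] result.
#' @return a [va_records] object, one row per label.
#' @export
generate_va_records <- function(labels, model) {
  stopifnot(inherits(model, "symptom_model"))
  rs <- model$ruleset
  n <- nrow(labels)
  bin <- rs$symptoms$symptom_id[rs$symptoms$type == "binary"]
  num <- rs$symptoms$symptom_id[rs$symptoms$type == "numeric"]
  df <- data.frame(death_id = labels$death_id, stringsAsFactors = FALSE)
  for (s in bin) df[[s]] <- rep("no", n)
  for (s in num) df[[s]] <- rep(0, n)
  fixed <- matrix(FALSE, n, length(bin), dimnames = list(NULL, bin))

  apply_sig <- function(i, sig) {
    for (s in names(sig)) {
      df[i, s] <<- sig[[s]]
      if (s %in% bin) fixed[i, s] <<- TRUE
    }
  }
  cause_sets <- split_causes(labels$causes)
  sens_draw <- stats::runif(n) < model$sensitivity
  for (i in seq_len(n)) {
    true <- intersect(cause_sets[[i]], names(model$signatures))
    if (sens_draw[i]) for (cz in true) apply_sig(i, model$signatures[[cz]])
    foreign <- setdiff(names(model$signatures), cause_sets[[i]])
    leak <- foreign[stats::runif(length(foreign)) < 1 - model$specificity]
    for (cz in leak) apply_sig(i, model$signatures[[cz]])
  }
  if (model$background > 0 && length(bin)) {
    noise <- matrix(stats::runif(n * length(bin)) < model$background,
                    n, length(bin))
    flip <- noise & !fixed
    for (j in seq_along(bin)) {
      df[[bin[j]]][flip[, j]] <- "yes"
    }
  }
  va_records(df, labels_age_group(labels))
}

labels_age_group <- function(labels) {
  attr(labels, "age_group") %||% "neonate"
}

#' Default synthetic validation fixture
#'
#' One call producing a matched (rule set, reference labels, VA records)
#' triple for an age group: the paper-style cause lists with a plausible
#' high-mortality community CSMF, the enumerated co-morbid combinations
#' (neonate: preterm with asphyxia and/or sepsis; child:
#' pneumonia with diarrhea), and records generated at the requested
#' sensitivity/specificity.  Defaults: n = 1000, seed = 20160601.
#'
#' @param age_group `"neonate"` or `"child"`.
#' @param n number of deaths.
#' @param sensitivity,specificity,background symptom-model probabilities.
#' @param comorbid logical: include the co-morbid combinations.
#' @param seed RNG seed.
#' @return list with elements `ruleset`, `labels`, `records`, `model`,
#'   `config`.
#' @export
synthetic_fixture <- function(age_group = c("neonate", "child"), n = 1000L,
                              sensitivity = 1, specificity = 1,
                              background = 0, comorbid = TRUE,
                              seed = 20160601L) {
  age_group <- match.arg(age_group)
  ruleset <- demo_ruleset(age_group)
  if (age_group == "neonate") {
    csmf <- c(preterm_delivery = .30, birth_asphyxia = .25, sepsis = .20,
              pneumonia = .10, congenital_malformation = .08, meningitis = .07)
    rates <- list("preterm_delivery|birth_asphyxia" = .05,
                  "preterm_delivery|sepsis" = .05,
                  "preterm_delivery|sepsis|birth_asphyxia" = .02)
  } else {
    csmf <- c(pneumonia = .20, diarrhea = .15, malaria = .12, aids = .05,
              measles = .04, meningitis = .06, injury = .08,
              other_infectious = .15, non_infectious = .15)
    rates <- list("pneumonia|diarrhea" = .05)
  }
  if (!comorbid) rates <- list()
  config <- generator_config(age_group, csmf, rates, n)
  set.seed(seed)
  labels <- generate_reference_deaths(config)
  model <- build_symptom_model(ruleset, sensitivity, specificity, background)
  records <- generate_va_records(labels, model)
  list(ruleset = ruleset, labels = labels, records = records,
       model = model, config = config)
}
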