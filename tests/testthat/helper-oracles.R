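# Independent brute-force oracles.  These deliberately re-derive each
# quantity with the plainest possible code (loops, enumeration) and never
# call the package functions they are used to check.

# --- predicate evaluation on a single response list -------------------------
# responses: named list, values "yes"/"no"/"dont_know"/NA or numbers
oracle_eval <- function(pred, responses, dk_policy = "false") {
  keys <- names(pred)
  if ("all" %in% keys) {
    for (p in pred$all) if (!oracle_eval(p, responses, dk_policy)) return(FALSE)
    return(TRUE)
  }
  if ("any" %in% keys) {
    for (p in pred$any) if (oracle_eval(p, responses, dk_policy)) return(TRUE)
    return(FALSE)
  }
  if ("not" %in% keys) return(!oracle_eval(pred$not, responses, dk_policy))
  v <- responses[[pred$symptom]]
  if (!is.null(pred$is)) {
    if (is.null(v) || is.na(v)) v <- "missing"
    dk <- if (!is.null(pred$dk)) pred$dk else dk_policy
    if (pred$is == "yes") return(identical(v, "yes"))
    if (dk == "as_no") return(v %in% c("no", "dont_know", "missing"))
    return(identical(v, "no"))
  }
  if (is.null(v) || is.na(v) || !is.numeric(v)) return(FALSE)
  if (pred$op == ">=") v >= pred$value else v <= pred$value
}

# --- random rule-set configs ------------------------------------------------
random_atom <- function(sids) {
  s <- sample(sids, 1)
  list(symptom = s, is = sample(c("yes", "no"), 1))
}

random_predicate <- function(sids, depth = 2) {
  if (depth == 0 || runif(1) < 0.4) return(random_atom(sids))
  op <- sample(c("all", "any", "not"), 1)
  if (op == "not") return(list(not = random_predicate(sids, depth - 1)))
  k <- sample(2:3, 1)
  kids <- lapply(seq_len(k), function(i) random_predicate(sids, depth - 1))
  stats::setNames(list(kids), op)
}

random_ruleset_json <- function(n_symptoms = 5, n_rules = 3) {
  sids <- paste0("s", seq_len(n_symptoms))
  sym <- lapply(sids, function(s) list(type = "binary", label = paste("sym", s)))
  names(sym) <- sids
  rules <- lapply(seq_len(n_rules), function(i) {
    list(cause = paste0("cause_", i), predicate = random_predicate(sids))
  })
  jsonlite::toJSON(list(age_group = "neonate", dk_policy = "false",
                        symptoms = sym, rules = rules), auto_unbox = TRUE)
}

# --- integer allocations ----------------------------------------------------
# all k-part compositions of n
enum_allocations <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    rest <- enum_allocations(n - i, k - 1)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

# minimal total |alloc - quota| over all allocations (largest-remainder
# attains this minimum)
oracle_min_deviation <- function(shares, n) {
  quota <- n * shares / sum(shares)
  alls <- enum_allocations(n, length(shares))
  min(apply(alls, 1, function(a) sum(abs(a - quota))))
}

# --- agreement metrics ------------------------------------------------------
oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- 0
  for (i in seq_len(nrow(cm))) po <- po + cm[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(cm))) pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

oracle_ccc <- function(cm) {
  ref <- which(rowSums(cm) > 0)
  N <- length(ref)
  vals <- numeric(0)
  for (i in ref) {
    sens <- cm[i, i] / sum(cm[i, ])
    vals <- c(vals, (sens - 1 / N) / (1 - 1 / N))
  }
  mean(vals)
}

oracle_csmf_accuracy <- function(pred, true) {
  err <- 0
  for (j in seq_along(true)) err <- err + abs(pred[[j]] - true[[j]])
  1 - err / (2 * (1 - min(true)))
}

random_confusion <- function(k = NULL) {
  if (is.null(k)) k <- sample(2:6, 1)
  m <- matrix(rpois(k * k, 3) + ifelse(diag(k) == 1, rpois(k, 5), 0), k, k)
  # guarantee every cause has at least one reference death and margins vary
  diag(m) <- diag(m) + 1
  dimnames(m) <- list(paste0("c", 1:k), paste0("c", 1:k))
  m
}
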