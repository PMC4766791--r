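#' Cause-specific mortality fractions from individual labels
#'
#' @param labels named character vector `death_id` -> cause id.
#' @param cause_list ordered causes defining the distribution's support.
#'   Labels outside the list are counted under `"unspecified"` when it is
#'   present in the list, otherwise they raise an error.
#' @return a [cause_distribution] over `cause_list`.
#' @export
csmf_from_labels <- function(labels, cause_list) {
  if (length(labels) == 0L) {
    hv_stop("cannot compute CSMFs from zero deaths", "hierVA_usage_error")
  }
  stray <- !(labels %in% cause_list)
  if (any(stray)) {
    if (!"unspecified" %in% cause_list) {
      hv_stop(sprintf("label(s) outside the cause list: %s",
                      paste(unique(labels[stray]), collapse = ", ")),
              "hierVA_usage_error")
    }
    labels[stray] <- "unspecified"
  }
  tab <- table(factor(labels, levels = cause_list))
  cause_distribution(stats::setNames(as.numeric(tab) / length(labels),
                                     cause_list))
}

align_fractions <- function(pred, true) {
  if (is.null(names(pred)) && is.null(names(true))) {
    if (length(pred) != length(true)) {
      hv_stop("unnamed CSMF vectors must have equal length",
              "hierVA_usage_error")
    }
    nm <- paste0("cause", seq_along(pred))
    names(pred) <- nm
    names(true) <- nm
  }
  causes <- union(names(true), names(pred))
  p <- stats::setNames(rep(0, length(causes)), causes)
  t <- p
  p[names(pred)] <- pred
  t[names(true)] <- true
  list(pred = p, true = t, causes = causes)
}

#' CSMF accuracy
#'
#' Population-level agreement between estimated and reference cause
#' fractions:
#' \deqn{1 - \frac{\sum_j |CSMF^{pred}_j - CSMF^{true}_j|}
#'                {2\,(1 - \min_j CSMF^{true}_j)}}
#' The denominator is the largest total absolute error attainable given the
#' smallest true cause fraction, so the statistic lies in \[0, 1\] for
#' proper distributions and equals 1 exactly when the distributions are
#' identical.  Raw (not necessarily normalized) fraction vectors are
#' accepted, matching how published worked examples quote rounded
#' percentages.
#'
#' @param pred,true numeric vectors of cause fractions; aligned by name
#'   (absent causes count as 0) or by position when both are unnamed.
#' @return CSMF accuracy as a single number.
#' @examples
#' csmf_accuracy(c(a = .52, b = .29, c = .02, d = .04),
#'               c(a = .32, b = .31, c = .11, d = .11))  # 0.786...
#' @export
csmf_accuracy <- function(pred, true) {
  al <- align_fractions(pred, true)
  if (length(al$causes) < 2L) {
    hv_stop("CSMF accuracy needs at least two causes", "hierVA_metric_error")
  }
  mn <- min(al$true)
  if (1 - mn <= 0) {
    hv_stop("CSMF accuracy undefined: reference mass concentrated on one cause",
            "hierVA_metric_error")
  }
  1 - sum(abs(al$pred - al$true)) / (2 * (1 - mn))
}

#' Per-cause absolute CSMF difference
#'
#' @inheritParams csmf_accuracy
#' @return named numeric vector `|pred_j - true_j|` per cause.
#' @export
csmf_abs_diff <- function(pred, true) {
  al <- align_fractions(pred, true)
  abs(al$pred - al$true)
}

#' Confusion matrix of reference versus predicted causes
#'
#' @param true,pred character vectors (or named vectors aligned by
#'   `death_id` when both are named) of reference and predicted causes.
#' @param cause_list optional ordered cause list; defaults to the sorted
#'   union of observed causes.
#' @return a `confusion_matrix`: an integer matrix with true causes in rows
#'   and predicted causes in columns.
#' @export
confusion_matrix <- function(true, pred, cause_list = NULL) {
  if (!is.null(names(true)) && !is.null(names(pred))) {
    if (!setequal(names(true), names(pred))) {
      hv_stop("true and pred label different deaths", "hierVA_usage_error")
    }
    pred <- pred[names(true)]
  }
  if (length(true) != length(pred)) {
    hv_stop("true and pred must have equal length", "hierVA_usage_error")
  }
  if (is.null(cause_list)) cause_list <- sort(union(true, pred))
  m <- table(factor(true, levels = cause_list),
             factor(pred, levels = cause_list))
  structure(unclass(m), class = c("confusion_matrix", "matrix"))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o} the diagonal fraction and expected
#' agreement \eqn{p_e = \sum_j r_j c_j / n^2} from the row and column
#' marginals.  Ranges over \[-1, 1\]; 1 for perfect agreement.
#'
#' @param cm a [confusion_matrix] (any square count matrix is accepted).
#' @return kappa as a single number.
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 1) hv_stop("empty confusion matrix", "hierVA_metric_error")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    hv_stop("kappa undefined: both margins concentrated on one cause",
            "hierVA_metric_error")
  }
  (po - pe) / (1 - pe)
}

#' Chance-corrected concordance (CCC)
#'
#' Individual-level agreement: per-cause sensitivity corrected for the
#' chance agreement rate \eqn{1/N},
#' \deqn{CCC_j = \frac{sens_j - 1/N}{1 - 1/N},}
#' averaged (unweighted) over the causes with at least one reference death.
#' `N` is the number of such causes, so the overall statistic spans
#' \eqn{1/(1-N)} to 1.  Causes that appear only as predictions (e.g. an
#' `"unspecified"` column) contribute misclassification through the rows of
#' the matrix but are not averaged.
#'
#' @param cm a [confusion_matrix].
#' @param per_cause return the per-cause CCC vector instead of the mean.
#' @return the overall CCC, or a named per-cause vector.
#' @export
chance_corrected_concordance <- function(cm, per_cause = FALSE) {
  cm <- as.matrix(cm)
  ref <- rowSums(cm) > 0
  N <- sum(ref)
  if (N < 2L) {
    hv_stop("CCC needs at least two causes with reference deaths",
            "hierVA_metric_error")
  }
  sens <- diag(cm)[ref] / rowSums(cm)[ref]
  ccc <- (sens - 1 / N) / (1 - 1 / N)
  if (per_cause) ccc else mean(ccc)
}
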