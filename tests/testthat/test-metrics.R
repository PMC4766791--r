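# agreement metrics: CSMF accuracy, absolute differences, kappa, CCC

worked_pred <- c(sepsis_pneumonia = .52, birth_asphyxia = .29,
                 congenital_malformation = .02, preterm_delivery = .04)
worked_true <- c(sepsis_pneumonia = .32, birth_asphyxia = .31,
                 congenital_malformation = .11, preterm_delivery = .11)

test_that("the four-cause worked example gives CSMF accuracy 0.79", {
  expect_equal(round(csmf_accuracy(worked_pred, worked_true), 2), 0.79)
  # and sepsis/pneumonia is overestimated by 0.20
  d <- csmf_abs_diff(worked_pred, worked_true)
  expect_equal(unname(d["sepsis_pneumonia"]), 0.20)
})

test_that("CSMF accuracy boundary behaviour", {
  t1 <- c(A = .8, B = .2)
  expect_equal(csmf_accuracy(t1, t1), 1)
  # hand evaluation: total error .6, denominator 2*(1-.2)=1.6
  expect_equal(csmf_accuracy(c(A = .5, B = .5), t1), 0.625)
  # 1 iff identical
  expect_lt(csmf_accuracy(c(A = .80001, B = .19999), t1), 1)
  # invariant to cause relabelling
  expect_equal(csmf_accuracy(worked_pred, worked_true),
               csmf_accuracy(stats::setNames(worked_pred, letters[1:4]),
                             stats::setNames(worked_true, letters[1:4])))
  # symmetric absolute differences
  expect_equal(csmf_abs_diff(worked_pred, worked_true),
               csmf_abs_diff(worked_true, worked_pred))
  expect_true(all(csmf_abs_diff(worked_true, worked_true) == 0))
  # degenerate inputs: fewer than two causes is undefined; a zero-fraction
  # cause is fine (min_true = 0 keeps the denominator positive)
  expect_error(csmf_accuracy(c(A = 1), c(A = 1)), class = "hierVA_metric_error")
  expect_equal(csmf_accuracy(c(A = 1, B = 0), c(A = 1, B = 0)), 1)
})

test_that("kappa and CCC reproduce hand-derived cases", {
  cm <- matrix(c(40, 20, 10, 30), 2, 2,  # true x pred: [[40,10],[20,30]]
               dimnames = list(c("a", "b"), c("a", "b")))
  # p_o = .7, p_e = .5*.6 + .5*.4 = .5 -> kappa .4
  expect_equal(cohens_kappa(cm), 0.4)
  # sensitivities .8 and .6, chance 1/2 -> per-cause CCC .6, .2, mean .4
  expect_equal(chance_corrected_concordance(cm), 0.4)
  expect_equal(unname(chance_corrected_concordance(cm, per_cause = TRUE)),
               c(0.6, 0.2))
  diagm <- diag(c(5L, 7L, 9L))
  dimnames(diagm) <- list(letters[1:3], letters[1:3])
  expect_equal(cohens_kappa(diagm), 1)
  expect_equal(chance_corrected_concordance(diagm), 1)
  # a 2-cause always-wrong classifier attains the CCC floor 1/(1-N) = -1
  wrong <- matrix(c(0, 30, 70, 0), 2, 2)
  expect_equal(chance_corrected_concordance(wrong), -1)
  expect_error(cohens_kappa(matrix(c(10, 0, 0, 0), 2, 2)),
               class = "hierVA_metric_error")
  expect_error(chance_corrected_concordance(matrix(5)),
               class = "hierVA_metric_error")
})

test_that("kappa of independent labels is near zero at n = 10^4", {
  set.seed(61)
  true <- sample(letters[1:4], 1e4, replace = TRUE, prob = c(.4, .3, .2, .1))
  pred <- sample(letters[1:4], 1e4, replace = TRUE, prob = c(.1, .2, .3, .4))
  expect_lt(abs(cohens_kappa(confusion_matrix(true, pred))), 0.05)
})

test_that("all metrics agree with brute-force oracles on 100 random matrices", {
  set.seed(17)
  for (trial in 1:100) {
    cm <- random_confusion()
    expect_equal(cohens_kappa(cm), oracle_kappa(cm))
    expect_equal(chance_corrected_concordance(cm), oracle_ccc(cm))
    k <- nrow(cm)
    p <- runif(k); p <- p / sum(p)
    t <- runif(k); t <- t / sum(t)
    names(p) <- names(t) <- rownames(cm)
    acc <- csmf_accuracy(p, t)
    expect_equal(acc, oracle_csmf_accuracy(p, t))
    expect_gte(acc, 0)
    expect_lte(acc, 1)
    expect_gte(cohens_kappa(cm), -1)
    expect_lte(cohens_kappa(cm), 1)
    expect_gte(chance_corrected_concordance(cm), 1 / (1 - sum(rowSums(cm) > 0)))
    expect_lte(chance_corrected_concordance(cm), 1)
  }
})

test_that("kappa equals CCC for 2 causes with symmetric margins", {
  set.seed(29)
  for (trial in 1:20) {
    a <- sample(5:50, 1); b <- sample(5:50, 1)
    cm <- matrix(c(a, b, b, a), 2, 2)  # symmetric margins by construction
    expect_equal(cohens_kappa(cm), chance_corrected_concordance(cm))
  }
})

test_that("csmf_from_labels tallies correctly", {
  lab <- stats::setNames(rep("A", 10), sprintf("d%d", 1:10))
  expect_equal(unclass(csmf_from_labels(lab, c("A", "B"))), c(A = 1, B = 0))
  lab2 <- stats::setNames(rep(c("A", "B"), 5), sprintf("d%d", 1:10))
  expect_equal(unclass(csmf_from_labels(lab2, c("A", "B"))), c(A = .5, B = .5))
  set.seed(8)
  for (trial in 1:10) {
    causes <- paste0("c", 1:sample(2:5, 1))
    lab3 <- stats::setNames(sample(causes, 50, replace = TRUE),
                            sprintf("d%d", 1:50))
    got <- csmf_from_labels(lab3, causes)
    for (cz in causes) expect_equal(got[[cz]], sum(lab3 == cz) / 50)
  }
  expect_error(csmf_from_labels(character(0), c("A", "B")),
               class = "hierVA_usage_error")
  # stray labels count as unspecified when it is in the list
  lab4 <- c(d1 = "A", d2 = "weird")
  expect_equal(csmf_from_labels(lab4, c("A", "unspecified"))[["unspecified"]], .5)
})
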