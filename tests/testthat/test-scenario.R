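# mortality scenarios, target draws, apportionment, resampling

mini_table <- function() {
  df <- data.frame(country_id = c("a", "b", "c", "d"),
                   age_group = "neonate",
                   u5mr = c(30, 40, 36, 22),
                   malaria_fraction = c(0.10, 0.02, 0.06, 0.00),
                   sepsis = c(.5, .4, .3, .2),
                   preterm_delivery = c(.3, .4, .5, .6),
                   birth_asphyxia = c(.2, .2, .2, .2))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  read_country_table(path)
}

test_that("scenario filters apply the published thresholds", {
  tab <- mini_table()
  high <- eligible_rows(tab, scenario_spec("high_u5mr_no_malaria"))
  expect_identical(high$country_id, "b")        # u5mr 40 > 35, malaria 2% <= 5%
  hm <- eligible_rows(tab, scenario_spec("high_u5mr_malaria"))
  expect_identical(hm$country_id, "c")          # u5mr 36 > 35, malaria 6% > 5%
  mod <- eligible_rows(tab, scenario_spec("moderate_u5mr"))
  expect_setequal(mod$country_id, c("a", "d"))  # 20 <= u5mr <= 35
  # u5mr = 40 with malaria 2% is excluded from the malaria-endemic scenario
  expect_false("b" %in% hm$country_id)
  # boundary: u5mr 35 is moderate, not high
  tab35 <- tab; tab35$u5mr[1] <- 35
  expect_true("a" %in% eligible_rows(tab35, scenario_spec("moderate_u5mr"))$country_id)
  expect_error(eligible_rows(tab[tab$u5mr < 20, , drop = FALSE],
                             scenario_spec("moderate_u5mr")),
               class = "hierVA_scenario_error")
})

test_that("country draws return an eligible row's distribution verbatim", {
  tab <- mini_table()
  sc <- scenario_spec("high_u5mr_malaria")  # unique eligible row: c
  set.seed(5)
  d <- draw_target_csmf(sc, tab)
  expect_equal(unclass(d)[c("sepsis", "preterm_delivery", "birth_asphyxia")],
               c(sepsis = .3, preterm_delivery = .5, birth_asphyxia = .2))
  set.seed(99); d1 <- draw_target_csmf(scenario_spec("moderate_u5mr"), tab)
  set.seed(99); d2 <- draw_target_csmf(scenario_spec("moderate_u5mr"), tab)
  expect_identical(d1, d2)
})

test_that("general-scenario draws stay inside the 5%-40% bounds over 1000 seeds", {
  sc <- scenario_spec("general")
  causes <- c("a", "b", "c", "d")
  for (s in 1:1000) {
    set.seed(s)
    d <- draw_target_csmf(sc, causes = causes)
    set.seed(s)
    raw <- runif(4, 0.05, 0.40)   # replay the pre-normalization draw
    expect_true(all(raw >= 0.05 & raw <= 0.40))
    expect_equal(unname(unclass(d)), raw / sum(raw))
    expect_equal(sum(d), 1)
  }
})

test_that("renormalization drops unavailable causes and rescales", {
  t1 <- cause_distribution(c(A = .5, B = .3, C = .2))
  expect_equal(unclass(renormalize_over_available(t1, c("A", "B"))),
               c(A = .625, B = .375))
  # identity when all causes available
  expect_equal(unclass(renormalize_over_available(t1, c("A", "B", "C", "Z"))),
               unclass(t1))
  # the no-tetanus-in-pool case: tetanus mass dropped, rest rescaled
  t2 <- cause_distribution(c(neonatal_tetanus = .08, sepsis = .46,
                             preterm_delivery = .46))
  out <- renormalize_over_available(t2, c("sepsis", "preterm_delivery"))
  expect_false("neonatal_tetanus" %in% names(out))
  expect_equal(unname(unclass(out)), c(.5, .5))
  expect_error(renormalize_over_available(t1, "Z"),
               class = "hierVA_scenario_error")
})

test_that("apportion_counts is exact largest-remainder", {
  t1 <- cause_distribution(c(A = .5, B = .3, C = .2))
  expect_identical(apportion_counts(t1, 10), c(A = 5L, B = 3L, C = 2L))
  # floors 3/2/1 with remainders .5/.1/.4: the leftover unit goes to A
  expect_identical(apportion_counts(t1, 7), c(A = 4L, B = 2L, C = 1L))
  set.seed(7)
  for (k in 1:25) {
    f <- runif(sample(2:6, 1)); f <- f / sum(f)
    names(f) <- paste0("c", seq_along(f))
    n <- sample(1:500, 1)
    counts <- apportion_counts(cause_distribution(f), n)
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - n * f) < 1))
  }
})

test_that("resampling reproduces the apportioned counts exactly", {
  pool <- list(A = sprintf("a%03d", 1:100), B = sprintf("b%03d", 1:100))
  t1 <- cause_distribution(c(A = .5, B = .5))
  set.seed(3)
  ids <- resample_to_target(pool, t1, 10)
  expect_length(ids, 10L)
  expect_equal(sum(startsWith(ids, "a")), 5)
  expect_equal(sum(startsWith(ids, "b")), 5)
  expect_true(all(ids %in% unlist(pool)))
  # a cause with an empty pool is dropped and its mass reapportioned
  t2 <- cause_distribution(c(A = .4, B = .4, C = .2))
  pool$C <- character(0)
  set.seed(3)
  ids2 <- resample_to_target(pool, t2, 10)
  expect_equal(sum(startsWith(ids2, "a")), 5)
  expect_equal(sum(startsWith(ids2, "b")), 5)
  # determinism under a fixed seed
  set.seed(12); x <- resample_to_target(pool, t2, 50)
  set.seed(12); y <- resample_to_target(pool, t2, 50)
  expect_identical(x, y)
  # empirical CSMF of any resample equals counts/n exactly
  set.seed(9)
  t3 <- cause_distribution(c(A = .61, B = .39))
  n <- 97
  ids3 <- resample_to_target(pool[c("A", "B")], t3, n)
  counts <- apportion_counts(t3, n)
  expect_equal(sum(startsWith(ids3, "a")), unname(counts["A"]))
  expect_true(all(abs(counts / n - unclass(t3)) < 1 / n))
})

test_that("bundled synthetic country tables are valid and span all scenarios", {
  for (age in c("neonate", "child")) {
    tab <- read_country_table(age)
    expect_true(all(tab$age_group == age))
    for (sc in c("high_u5mr_malaria", "high_u5mr_no_malaria", "moderate_u5mr")) {
      expect_gt(nrow(eligible_rows(tab, scenario_spec(sc))), 0)
    }
  }
})
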