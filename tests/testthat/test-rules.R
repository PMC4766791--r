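# rules engine: parsing, predicate evaluation, dataset classification

simple_ruleset <- function(dk_policy = "false") {
  parse_ruleset(sprintf('{
    "age_group": "neonate",
    "dk_policy": "%s",
    "symptoms": {
      "s1": {"type": "binary"}, "s2": {"type": "binary"},
      "s3": {"type": "binary"}, "s4": {"type": "binary"},
      "dur": {"type": "numeric", "unit": "days"}
    },
    "rules": [
      {"cause": "X", "predicate": {"all": [{"symptom": "s1", "is": "yes"},
                                           {"symptom": "s2", "is": "yes"}]}},
      {"cause": "Y", "predicate": {"any": [{"symptom": "s3", "is": "yes"},
                                           {"symptom": "s4", "is": "yes"}]}},
      {"cause": "Z", "predicate": {"all": [{"symptom": "s1", "is": "no"},
                                           {"symptom": "dur", "op": ">=", "value": 3}]}}
    ]
  }', dk_policy))
}

rec <- function(..., age = "neonate") {
  va_records(data.frame(death_id = "d1", ..., stringsAsFactors = FALSE), age)
}

test_that("parse_ruleset builds validated rule sets and rejects bad configs", {
  rs <- simple_ruleset()
  expect_s3_class(rs, "ruleset")
  expect_named(rs$rules, c("X", "Y", "Z"))
  expect_equal(length(rs$rules$X$all), 2L)
  expect_equal(nrow(rs$symptoms), 5L)

  expect_error(parse_ruleset('{
    "age_group": "neonate",
    "symptoms": {"s1": {"type": "binary"}},
    "rules": [{"cause": "X", "predicate": {"symptom": "s9", "is": "yes"}}]
  }'), "s9", class = "hierVA_parse_error")
  expect_error(parse_ruleset('{
    "age_group": "neonate",
    "symptoms": {"s1": {"type": "binary"}},
    "rules": [{"cause": "X", "predicate": {"nand": []}}]
  }'), class = "hierVA_parse_error")
  expect_error(parse_ruleset('{
    "age_group": "neonate",
    "symptoms": {"d": {"type": "numeric"}},
    "rules": [{"cause": "X", "predicate": {"symptom": "d", "op": ">", "value": 1}}]
  }'), class = "hierVA_parse_error")
  expect_error(parse_ruleset("not json at all {"), class = "hierVA_parse_error")
})

test_that("serialize/parse round-trips 50 random rule sets", {
  set.seed(11)
  for (i in 1:50) {
    txt <- random_ruleset_json(n_symptoms = sample(3:6, 1),
                               n_rules = sample(1:4, 1))
    rs <- parse_ruleset(txt)
    rs2 <- parse_ruleset(serialize_ruleset(rs))
    expect_equal(rs2, rs)
  }
})

test_that("evaluate_record returns all fired causes", {
  rs <- simple_ruleset()
  allno <- rec(s1 = "no", s2 = "no", s3 = "no", s4 = "no", dur = 0)
  expect_identical(evaluate_record(allno, rs), character(0))  # s1=no but dur<3
  expect_setequal(evaluate_record(rec(s1 = "yes", s2 = "yes", s3 = "no",
                                      s4 = "no", dur = 0), rs), "X")
  expect_setequal(evaluate_record(rec(s1 = "yes", s2 = "yes", s3 = "yes",
                                      s4 = "no", dur = 0), rs), c("X", "Y"))
  expect_setequal(evaluate_record(rec(s1 = "no", s2 = "no", s3 = "no",
                                      s4 = "no", dur = 5), rs), "Z")
})

test_that("missing and dont_know atoms follow the dont-know policy", {
  rs <- simple_ruleset()
  # default policy: any atom referencing missing/dont_know is false
  r <- rec(s1 = "dont_know", s2 = "yes", s3 = NA_character_, s4 = "no", dur = 5)
  expect_identical(evaluate_record(r, rs), character(0))  # s1 kills X and Z
  # as_no: dont_know/missing satisfy is:no atoms (Z needs s1 = no)
  rs2 <- simple_ruleset(dk_policy = "as_no")
  expect_setequal(evaluate_record(r, rs2), "Z")
  # but is:yes atoms still require an explicit yes
  expect_false("X" %in% evaluate_record(r, rs2))
})

test_that("evaluate_record agrees with truth-table enumeration", {
  # exhaustive over all 3^k response combinations for random small rule sets
  set.seed(23)
  for (trial in 1:10) {
    txt <- random_ruleset_json(n_symptoms = 4, n_rules = 2)
    rs <- parse_ruleset(txt)
    sids <- rs$symptoms$symptom_id
    grid <- expand.grid(rep(list(c("yes", "no", "dont_know")), length(sids)),
                        stringsAsFactors = FALSE)
    names(grid) <- sids
    grid$death_id <- sprintf("g%03d", seq_len(nrow(grid)))
    fired <- evaluate_records(va_records(grid, "neonate"), rs)
    for (i in seq_len(nrow(grid))) {
      for (cz in names(rs$rules)) {
        expect_identical(unname(fired[i, cz]),
                         oracle_eval(rs$rules[[cz]],
                                     as.list(grid[i, sids, drop = FALSE]),
                                     rs$dk_policy))
      }
    }
  }
})

test_that("age-group mismatch is a usage error", {
  rs <- simple_ruleset()
  r <- rec(s1 = "yes", s2 = "yes", s3 = "no", s4 = "no", dur = 0, age = "child")
  expect_error(evaluate_record(r, rs), class = "hierVA_usage_error")
})

test_that("classify_dataset is deterministic and validates inputs", {
  rs <- simple_ruleset()
  h <- hierarchy("demo", "neonate", list("X", "Y", "Z"))
  empty <- va_records(data.frame(death_id = character(0), s1 = character(0),
                                 s2 = character(0), s3 = character(0),
                                 s4 = character(0),
                                 dur = numeric(0)), "neonate")
  expect_length(classify_dataset(empty, rs, h), 0L)

  df <- data.frame(death_id = c("a", "b", "c"),
                   s1 = c("yes", "no", "no"), s2 = c("yes", "no", "no"),
                   s3 = c("no", "yes", "no"), s4 = "no",
                   dur = c(0, 0, 9), stringsAsFactors = FALSE)
  recs <- va_records(df, "neonate")
  out <- classify_dataset(recs, rs, h)
  expect_identical(out, c(a = "X", b = "Y", c = "Z"))
  expect_identical(classify_dataset(recs, rs, h), out)  # pure function

  dup <- df; dup$death_id <- c("a", "a", "c")
  expect_error(va_records(dup, "neonate"), class = "hierVA_input_error")
})

test_that("records round-trip through CSV with Y/N/DK coding", {
  df <- data.frame(death_id = c("a", "b"), s1 = c("yes", "dont_know"),
                   s2 = c("no", NA), dur = c(1.5, 0), stringsAsFactors = FALSE)
  recs <- va_records(df, "neonate")
  path <- withr::local_tempfile(fileext = ".csv")
  write_va_records(recs, path)
  back <- read_va_records(path, "neonate")
  expect_equal(as.data.frame(back), as.data.frame(recs))
  expect_error(va_records(data.frame(death_id = "a", s1 = "maybe"), "neonate"),
               class = "hierVA_input_error")
})
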