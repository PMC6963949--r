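reference_record <- function() {
  co <- generate_cohort(default_cohort_spec(1, 0), seed = 1)
  co[1, ]
}

test_that("the shipped reference model has 15 rules and the known cut-offs", {
  rs <- diabetes_rules()
  expect_s3_class(rs, "ruleset")
  expect_length(rs$rules, 15)
  expect_equal(vapply(rs$rules, `[[`, "", "id"), paste0("R", 1:15))
  expect_equal(extract_thresholds(rs, "UACR"), c(6.1, 71))
  expect_equal(extract_thresholds(rs, "HbA1c"), c(5.6, 5.8, 6.1, 6.4))
  r15 <- rs$rules[[15]]
  expect_length(r15$conditions, 1)
  expect_equal(r15$conditions[[1]]$attribute, "HbA1c")
  expect_equal(r15$conditions[[1]]$op, "gt")
  expect_equal(r15$conditions[[1]]$value, 6.4)
  expect_equal(r15$consequent, "diabetes")
  r6_attrs <- vapply(rs$rules[[6]]$conditions, `[[`, "", "attribute")
  expect_true("UACR" %in% r6_attrs)
})

test_that("worked rule applications route to the expected rules", {
  rs <- diabetes_rules()
  rec <- reference_record()
  rec$HbA1c <- 6.2; rec$LDL <- 120; rec$FPG <- 100
  rec$Race <- factor("Non-Hispanic Black", levels = levels(rec$Race))
  rec$UACR <- 5.0
  hit <- apply_rules(rs, rec)
  expect_equal(hit$class, "prediabetes")
  expect_equal(hit$rule, "R11")

  rec$HbA1c <- 7.0
  hit <- apply_rules(rs, rec)
  expect_equal(hit$class, "diabetes")
  expect_equal(hit$rule, "R15")

  rec$HbA1c <- 5.5; rec$FPG <- 130; rec$UACR <- 70.0
  hit <- apply_rules(rs, rec)
  expect_equal(hit$class, "prediabetes")
  expect_equal(hit$rule, "R6")

  rec$UACR <- 71.01
  hit <- apply_rules(rs, rec)
  expect_equal(hit$class, "diabetes")
  expect_equal(hit$rule, "R7")
})

test_that("the reference rules cover every in-range record exactly once", {
  co <- generate_cohort(default_cohort_spec(5000, 5000), seed = 8)
  rs <- diabetes_rules()
  st <- rule_stats(rs, co)
  expect_equal(attr(st, "uncovered"), 0)
  expect_equal(sum(st$support), 1, tolerance = 1e-12)
  expect_equal(sum(st$n_covered), nrow(co))
})

test_that("rule statistics follow first-match semantics and conventions", {
  co <- generate_cohort(default_cohort_spec(50, 0), seed = 9)
  all_d <- ruleset(list(rule("R1", list(condition("HbA1c", "gt", value = 0)),
                             "diabetes")))
  st <- rule_stats(all_d, co)
  expect_equal(st$support, 1)
  expect_equal(st$error, 0)

  nothing <- ruleset(list(
    rule("R1", list(condition("HbA1c", "gt", value = 100)), "diabetes"),
    rule("R2", list(), "diabetes")))
  st2 <- rule_stats(nothing, co)
  expect_equal(st2$support, c(0, 1))
  expect_equal(st2$error[1], 0)   # empty coverage counts no errors

  expect_error(rule_stats(all_d, co[0, ]), "empty")
})

test_that("threshold extraction validates the attribute and ignores order", {
  rs <- diabetes_rules()
  shuffled <- rs
  set.seed(1)
  shuffled$rules <- sample(rs$rules)
  expect_equal(extract_thresholds(shuffled, "UACR"),
               extract_thresholds(rs, "UACR"))
  expect_error(extract_thresholds(rs, "NotAnAttr"), "unknown")
  expect_error(extract_thresholds(rs, "Race"), "non-continuous")
  empty <- ruleset(list())
  expect_equal(extract_thresholds(empty, "UACR"), numeric(0))
})

test_that("tree-derived rule sets are order-invariant under first match", {
  co <- generate_cohort(default_cohort_spec(300, 300), seed = 10)
  fit <- c45(class ~ HbA1c + FPG + LDL + Race, co,
             tree_config(max_depth = 4))
  rs <- as_ruleset(fit)
  shuffled <- rs
  set.seed(2)
  shuffled$rules <- sample(rs$rules)
  a <- apply_rules(rs, co)
  b <- apply_rules(shuffled, co)
  expect_equal(a$class, b$class)
})

test_that("text serialization round-trips exactly", {
  rs <- diabetes_rules()
  expect_identical(serialize_rules(parse_rules(serialize_rules(rs))),
                   serialize_rules(rs))
  one <- parse_rules("IF HbA1c > 6.4 THEN diabetes")
  expect_length(one$rules, 1)
  expect_length(one$rules[[1]]$conditions, 1)
  two <- parse_rules("IF HbA1c in (5.8, 6.1] AND FPG <= 122.7 THEN diabetes")
  ops <- vapply(two$rules[[1]]$conditions, `[[`, "", "op")
  expect_equal(ops, c("in", "le"))
  expect_equal(two$rules[[1]]$conditions[[1]]$low, 5.8)
  expect_equal(two$rules[[1]]$conditions[[2]]$value, 122.7)

  # random rule sets round-trip too
  set.seed(3)
  for (rep in 1:10) {
    rules <- lapply(1:3, function(i) {
      conds <- list(condition("HbA1c", "le", value = round(runif(1, 4, 9), 3)),
                    condition("Race", "eq",
                              level = sample(levels(generate_cohort(
                                default_cohort_spec(1, 0), 1)$Race), 1)),
                    condition("FPG", "in", low = 60, high = 60 + runif(1, 1, 300)))
      rule(sprintf("R%d", i), sample(conds, sample(1:3, 1)),
           sample(c("diabetes", "prediabetes"), 1))
    })
    rs2 <- ruleset(rules)
    expect_identical(serialize_rules(parse_rules(serialize_rules(rs2))),
                     serialize_rules(rs2))
  }
})

test_that("JSON serialization round-trips and malformed text errors point home", {
  rs <- diabetes_rules()
  path <- withr::local_tempfile(fileext = ".json")
  write_rules_json(rs, path)
  expect_identical(serialize_rules(read_rules_json(path)),
                   serialize_rules(rs))
  expect_error(parse_rules("IF HbA1c >> 5 THEN diabetes"), "line 1")
  expect_error(parse_rules("R1: IF HbA1c <= x THEN diabetes"), "non-numeric")
  expect_error(parse_rules("HbA1c > 5"), "line 1")
})

test_that("uncovered records are reported explicitly, never defaulted", {
  co <- generate_cohort(default_cohort_spec(10, 10), seed = 11)
  partial <- ruleset(list(
    rule("R1", list(condition("HbA1c", "gt", value = 1000)), "diabetes")))
  hit <- apply_rules(partial, co)
  expect_true(all(is.na(hit$class)))
  expect_true(all(hit$rule == "(uncovered)"))
})
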