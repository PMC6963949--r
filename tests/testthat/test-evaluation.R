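oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  pairs <- outer(pos, neg, function(p, q)
    ifelse(p > q, 1, ifelse(p == q, 0.5, 0)))
  mean(pairs)
}

test_that("AUC equals exhaustive pair counting", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.3, 0.2), c("b", "b", "a", "a")), 1)
  expect_equal(auc_roc(c(0.1, 0.2, 0.8, 0.9), c("b", "b", "a", "a")), 0)
  s6 <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.7)
  l6 <- c("a", "b", "a", "b", "a", "b")
  expect_equal(auc_roc(s6, l6), oracle_auc(s6, l6, "b"))
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    sc <- round(runif(n), 2)    # rounding forces ties
    lb <- factor(sample(c("a", "b"), n, replace = TRUE))
    if (nlevels(droplevels(lb)) < 2) next
    expect_equal(auc_roc(sc, lb), oracle_auc(sc, lb, "b"),
                 tolerance = 1e-12)
  }
  expect_error(auc_roc(c(1, 2), c("a", "a")), "both classes")
  expect_error(auc_roc(c(1, NA), c("a", "b")), "finite")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  sc <- rnorm(50)
  lb <- factor(sample(c("a", "b"), 50, replace = TRUE))
  base <- auc_roc(sc, lb)
  expect_equal(auc_roc(exp(sc), lb), base)
  expect_equal(auc_roc(2 * sc + 7, lb), base)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(43)
  sc <- runif(100)
  lb <- factor(ifelse(runif(100) < plogis(3 * sc - 1.5), "b", "a"))
  want <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lb, sc, levels = c("a", "b"),
                        direction = "<"))))
  expect_equal(auc_roc(sc, lb, positive = "b"), want, tolerance = 1e-12)
})

test_that("stratified folds partition the cohort with balanced classes", {
  co <- generate_cohort(default_cohort_spec(120, 80), seed = 44)
  set.seed(1)
  fold <- rerx:::stratified_folds(co$class, 5)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 200)
  overall <- mean(co$class == "diabetes")
  for (f in 1:5) {
    tab <- table(co$class[fold == f])
    n_f <- sum(tab)
    # class counts within one record of the proportional share
    expect_lte(abs(tab[["diabetes"]] - overall * n_f), 1)
  }
  expect_error(rerx:::stratified_folds(factor(rep(c("a", "b"), c(3, 50))), 5),
               "larger cohort")
})

test_that("cross-validation reaches 100% on separable planted data", {
  p <- make_planted_cohort(600, seed = 45, noise = 0, model = "hba1c_only")
  cv <- cross_validate(p$data, rerx_config(), k = 3, runs = 1, seed = 1)
  expect_equal(nrow(cv$cells), 3)
  expect_equal(unname(cv$summary$test_acc["mean"]), 100)
})

test_that("label-shuffled data scores near the majority rate", {
  co <- generate_cohort(default_cohort_spec(), seed = 46)
  sh <- as.data.frame(co)
  set.seed(2)
  sh$class <- sample(sh$class)
  attr(sh, "schema") <- attr(co, "schema")
  cv <- cross_validate(sh, rerx_config(), k = 5, runs = 1, seed = 3)
  maj <- 100 * max(table(sh$class)) / nrow(sh)
  expect_lt(abs(unname(cv$summary$test_acc["mean"]) - maj), 3)
})

test_that("CV summary reproduces its cells and fold structure", {
  p <- make_planted_cohort(300, seed = 47, noise = 0.05,
                           model = "hba1c_only")
  cv <- cross_validate(p$data, rerx_config(), k = 2, runs = 2, seed = 4)
  expect_equal(nrow(cv$cells), 4)
  expect_equal(unname(cv$summary$test_acc["mean"]), mean(cv$cells$test_acc))
  expect_equal(unname(cv$summary$test_acc["sd"]), sd(cv$cells$test_acc))
  expect_equal(unname(cv$summary$n_rules["mean"]), mean(cv$cells$n_rules))
  expect_true(all(cv$cells$auc >= 0 & cv$cells$auc <= 1))
  expect_error(cross_validate(p$data, rerx_config(), k = 1), "k must be")
})

test_that("rule purity scores are Laplace-shrunk and rank consistent", {
  p <- make_planted_cohort(800, seed = 48, noise = 0, model = "hba1c_only")
  fit <- extract_rules(p$data, rerx_config(), seed = 5)
  sc <- rule_based_scores(fit, p$data)
  expect_true(all(sc > 0 & sc < 1))
  # scores reproduce rule ranking by positive-class purity
  hit <- predict(fit, p$data, type = "rule")
  agg <- tapply(p$data$class == "prediabetes", hit$rule, mean)
  srt <- tapply(sc, hit$rule, unique)
  common <- intersect(names(agg), names(srt))
  expect_equal(order(agg[common]), order(unlist(srt)[common]))
  # pure-rule records score near 1, and AUC on separable data is 1
  expect_equal(auc_roc(sc, p$data$class, positive = "prediabetes"), 1)
})

test_that("group comparison matches the attribute kinds and closed forms", {
  co <- generate_cohort(default_cohort_spec(), seed = 49)
  gc <- compare_groups(co)
  expect_equal(nrow(gc), 19)
  hba1c <- gc[gc$attribute == "HbA1c", ]
  expect_equal(hba1c$test, "Welch t")
  expect_lt(hba1c$p_value, 1e-4)
  expect_equal(gc[gc$attribute == "UACR", "test"], "Wilcoxon rank-sum")
  expect_equal(gc[gc$attribute == "Race", "test"], "chi-square")

  # identical groups: p near 1 everywhere a test is defined
  half <- as.data.frame(co[co$class == "diabetes", ])[1:300, ]
  dup <- rbind(half, half)
  dup$class <- rep(c("diabetes", "prediabetes"), each = 300)
  attr(dup, "schema") <- attr(co, "schema")
  gci <- compare_groups(dup)
  expect_true(all(gci$p_value > 0.99, na.rm = TRUE))

  # chi-square on a fixed 2x2 table against the closed-form
  # (Yates-corrected) statistic computed by hand
  tab <- matrix(c(30, 20, 10, 40), 2)   # rows No/Yes, cols the classes
  d2 <- data.frame(
    Exercise = factor(rep(rep(c("No", "Yes"), 2), c(30, 20, 10, 40))),
    class = rep(c("diabetes", "prediabetes"), c(50, 50)))
  gc2 <- compare_groups(d2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  yates <- sum((abs(tab - e) - 0.5)^2 / e)
  expect_equal(gc2$statistic[gc2$attribute == "Exercise"], yates,
               tolerance = 1e-12)
})

test_that("constant attributes are flagged instead of tested", {
  co <- as.data.frame(generate_cohort(default_cohort_spec(40, 40), seed = 50))
  co$HbA1c <- 5.0
  gc <- compare_groups(co)
  expect_equal(gc[gc$attribute == "HbA1c", "test"], "none (constant)")
  expect_true(is.na(gc[gc$attribute == "HbA1c", "p_value"]))
})
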