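# Cohorts labelled by small planted rule models, used for
# structure-recovery tests: attributes drawn uniformly over clinically
# plausible ranges, labels from an axis-aligned rule model, optional
# label noise.

planted_models <- list(
  hba1c_only = list(
    label = function(d) ifelse(d$HbA1c > 6.4, "diabetes", "prediabetes"),
    thresholds = list(HbA1c = 6.4),
    attrs = c("HbA1c", "FPG")),
  hba1c_fpg = list(
    label = function(d) ifelse(d$HbA1c > 6.4 | d$FPG > 125,
                               "diabetes", "prediabetes"),
    thresholds = list(HbA1c = 6.4, FPG = 125),
    attrs = c("HbA1c", "FPG", "LDL")),
  hba1c_uacr = list(
    label = function(d) ifelse(d$HbA1c > 7.0,
                               "diabetes",
                               ifelse(d$UACR > 71, "diabetes", "prediabetes")),
    thresholds = list(HbA1c = 7.0, UACR = 71),
    attrs = c("HbA1c", "UACR", "LDL", "FPG"))
)

planted_ranges <- list(HbA1c = c(3.5, 17.5), FPG = c(51, 421),
                       LDL = c(14, 375), UACR = c(0.21, 300))

make_planted_cohort <- function(n, seed, noise = 0, model = "hba1c_only") {
  m <- planted_models[[model]]
  set.seed(seed)
  d <- as.data.frame(lapply(planted_ranges[m$attrs], function(r)
    stats::runif(n, r[1], r[2])))
  names(d) <- m$attrs
  lab <- m$label(d)
  if (noise > 0) {
    flip <- stats::runif(n) < noise
    lab[flip] <- ifelse(lab[flip] == "diabetes", "prediabetes", "diabetes")
  }
  d$class <- factor(lab, levels = c("diabetes", "prediabetes"))
  list(data = d, model = m)
}

# Finest threshold resolution the data admit around a planted cut t:
# the gap between the nearest observed values on either side of t.
threshold_gap <- function(values, t) {
  lo <- max(values[values <= t])
  hi <- min(values[values > t])
  c(lo = lo, hi = hi)
}

recovers_threshold <- function(rules, attribute, t, values) {
  th <- extract_thresholds(rules, attribute)
  if (length(th) == 0) return(FALSE)
  g <- threshold_gap(values, t)
  any(th >= g["lo"] - 1e-9 & th <= g["hi"] + 1e-9)
}

# independent entropy oracle used by the gain-ratio equivalence tests:
# plain textbook formula over an explicit contingency table
oracle_gain_ratio <- function(a, b, c_, d) {
  H <- function(x) {
    x <- x[x > 0]; n <- sum(x)
    if (n == 0) return(0)
    -sum((x / n) * log2(x / n))
  }
  n <- a + b + c_ + d
  gain <- H(c(a + c_, b + d)) -
    ((a + b) / n) * H(c(a, b)) - ((c_ + d) / n) * H(c(c_, d))
  si <- H(c(a + b, c_ + d))
  if (gain <= 0 || si <= 0) 0 else gain / si
}

# build a tiny cohort realizing the 2x2 table: left branch (x <= 0.5)
# holds a positives / b negatives, right branch c_ / d
table_cohort <- function(a, b, c_, d) {
  data.frame(
    x = c(rep(0, a + b), rep(1, c_ + d)),
    class = c(rep("diabetes", a), rep("prediabetes", b),
              rep("diabetes", c_), rep("prediabetes", d)))
}
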