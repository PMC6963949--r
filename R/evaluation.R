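#' Area under the ROC curve (rank statistic)
#'
#' Computed as the Mann-Whitney U probability that a randomly chosen
#' positive-class record outscores a randomly chosen negative-class
#' record, with ties counted one half -- i.e. via average ranks, which
#' makes the value invariant under strictly monotone score transforms.
#'
#' @param scores numeric scores (higher = more positive-class).
#' @param labels class labels; \code{positive} defaults to the second
#'   factor level.
#' @param positive the positive class label.
#' @return AUC in [0, 1].
#' @examples
#' auc_roc(c(0.9, 0.8, 0.3, 0.2), c("b", "b", "a", "a"))  # 1
#' @export
auc_roc <- function(scores, labels, positive = NULL) {
  if (any(!is.finite(scores))) stop("auc_roc: scores must be finite")
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("auc_roc: both classes must be present")
  positive <- positive %||% levels(labels)[2]
  pos <- labels == positive
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: within each class, shuffle and deal into k
# folds round-robin, so per-fold class proportions are within one record
# of the cohort proportions
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop(sprintf("cross_validate: class '%s' has %d record(s), fewer than k = %d; use a larger cohort",
                   cls, length(idx), k))
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the Re-RX pipeline
#'
#' Runs \code{runs} independent repetitions of stratified k-fold CV
#' (defaults 10 x 5, the study protocol): per run-fold cell the full
#' pipeline is fitted on the training split and evaluated on the
#' held-out split.  Reported per cell: training and test accuracy (%),
#' number of extracted rules, and
#' test AUC-ROC from Laplace-corrected rule-purity scores.  Aggregates
#' are mean and SD over all run x fold cells; a pooled AUC over the
#' concatenated held-out scores of all cells is reported alongside the
#' cell-mean AUC.
#'
#' @param cohort labelled cohort.
#' @param config a [rerx_config()].
#' @param k number of folds (>= 2).
#' @param runs number of repetitions.
#' @param seed integer; expands into per-run shuffles and per-cell
#'   network seeds.
#' @return a \code{cv_report}: \code{$cells} data frame and
#'   \code{$summary} list.
#' @export
cross_validate <- function(cohort, config = rerx_config(), k = 5,
                           runs = 10, seed = 1) {
  if (k < 2) stop("cross_validate: k must be >= 2")
  data <- as.data.frame(cohort)
  data$class <- factor(data$class)
  schema <- attr(cohort, "schema") %||% infer_schema(data)
  cells <- list()
  pooled_scores <- numeric(0)
  pooled_labels <- character(0)
  for (run in seq_len(runs)) {
    fold <- with_seed(derive_seed(seed, "folds", run),
                      stratified_folds(data$class, k))
    for (f in seq_len(k)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      attr(train, "schema") <- schema
      fit <- extract_rules(train, config,
                           seed = derive_seed(seed, "net", run, f))
      pred_test <- predict(fit, test)
      sc <- rule_based_scores(fit, test)
      cells[[length(cells) + 1]] <- data.frame(
        run = run, fold = f,
        train_acc = 100 * fit$train_accuracy,
        test_acc = 100 * mean(as.character(pred_test) ==
                                as.character(test$class)),
        n_rules = length(fit$rules$rules),
        auc = auc_roc(sc, test$class, positive = fit$positive_class))
      pooled_scores <- c(pooled_scores, sc)
      pooled_labels <- c(pooled_labels, as.character(test$class))
    }
  }
  cells <- do.call(rbind, cells)
  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  summary <- list(train_acc = msd(cells$train_acc),
                  test_acc = msd(cells$test_acc),
                  n_rules = msd(cells$n_rules),
                  auc_pct = msd(100 * cells$auc),
                  pooled_auc_pct = 100 * auc_roc(
                    pooled_scores, factor(pooled_labels),
                    positive = levels(data$class)[2]),
                  k = k, runs = runs, n = nrow(data))
  structure(list(cells = cells, summary = summary), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d x %d-fold CV on %d records\n", s$runs, s$k, s$n))
  cat(sprintf("TR ACC %.2f +/- %.2f %% | TS ACC %.2f +/- %.2f %% | # rules %.2f | AUC-ROC %.1f %% (pooled %.1f %%)\n",
              s$train_acc["mean"], s$train_acc["sd"],
              s$test_acc["mean"], s$test_acc["sd"],
              s$n_rules["mean"], s$auc_pct["mean"], s$pooled_auc_pct))
  invisible(x)
}

#' Between-class comparison of cohort attributes
#'
#' Produces a per-attribute comparison of the two classes in the style
#' of a clinical baseline table: near-symmetric continuous attributes
#' are summarized as mean (SD) and tested with Welch's two-sample t-test
#' (a paired t-test is available but only meaningful for matched
#' designs); right-skewed continuous attributes are summarized by the
#' median and tested with the Wilcoxon rank-sum test; categorical
#' attributes are summarized as level percentages and tested with the
#' chi-square test.  Constant attributes are flagged and left untested.
#' No multiplicity correction is applied by default.
#'
#' @param cohort labelled cohort.
#' @param skewed attribute names to treat as right-skewed.
#' @param paired use a paired t-test (records must be matched in order).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()] (default \code{"none"}).
#' @return a \code{group_comparison} data frame: attribute, kind,
#'   per-class summary, test, statistic and p-value.
#' @export
compare_groups <- function(cohort,
                           skewed = c("UACR", "FPG", "Insulin", "Alcohol",
                                      "Triglycerides"),
                           paired = FALSE, p_adjust = "none") {
  data <- as.data.frame(cohort)
  schema <- attr(cohort, "schema") %||% infer_schema(data)
  y <- factor(data$class)
  cls <- levels(y)
  rows <- list()
  for (a in schema) {
    x <- data[[a$name]]
    g1 <- x[y == cls[1]]; g2 <- x[y == cls[2]]
    if (a$kind == "continuous") {
      if (stats::sd(as.numeric(x)) == 0) {
        rows[[a$name]] <- data.frame(attribute = a$name, kind = a$kind,
          summary_1 = format(mean(as.numeric(g1)), digits = 4),
          summary_2 = format(mean(as.numeric(g2)), digits = 4),
          test = "none (constant)", statistic = NA_real_,
          p_value = NA_real_)
        next
      }
      if (a$name %in% skewed) {
        tst <- stats::wilcox.test(as.numeric(g1), as.numeric(g2),
                                  exact = FALSE)
        s1 <- sprintf("median %.4g", stats::median(as.numeric(g1)))
        s2 <- sprintf("median %.4g", stats::median(as.numeric(g2)))
        nm <- "Wilcoxon rank-sum"
      } else {
        tst <- stats::t.test(as.numeric(g1), as.numeric(g2),
                             paired = paired)
        s1 <- sprintf("%.4g (%.3g)", mean(as.numeric(g1)),
                      stats::sd(as.numeric(g1)))
        s2 <- sprintf("%.4g (%.3g)", mean(as.numeric(g2)),
                      stats::sd(as.numeric(g2)))
        nm <- if (paired) "paired t" else "Welch t"
      }
      rows[[a$name]] <- data.frame(attribute = a$name, kind = a$kind,
        summary_1 = s1, summary_2 = s2, test = nm,
        statistic = unname(tst$statistic), p_value = tst$p.value)
    } else {
      tab <- table(factor(x, levels = a$levels), y)
      if (length(unique(as.character(x))) < 2) {
        rows[[a$name]] <- data.frame(attribute = a$name, kind = a$kind,
          summary_1 = "constant", summary_2 = "constant",
          test = "none (constant)", statistic = NA_real_,
          p_value = NA_real_)
        next
      }
      tst <- suppressWarnings(stats::chisq.test(tab[rowSums(tab) > 0, ]))
      pct <- function(col) paste(sprintf("%s %.1f%%", rownames(tab),
                                         100 * tab[, col] / sum(tab[, col])),
                                 collapse = ", ")
      rows[[a$name]] <- data.frame(attribute = a$name, kind = a$kind,
        summary_1 = pct(1), summary_2 = pct(2), test = "chi-square",
        statistic = unname(tst$statistic), p_value = tst$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  names(out)[names(out) == "summary_1"] <- paste0("summary_", cls[1])
  names(out)[names(out) == "summary_2"] <- paste0("summary_", cls[2])
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$p_value <- format.pval(df$p_value, digits = 3, eps = 1e-4)
  df$statistic <- signif(df$statistic, 4)
  print.data.frame(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
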