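#' C4.5 tree configuration
#'
#' Parameters of the tree-induction stage.  Defaults follow the classic
#' C4.5 release: minimum 2 records per branch and pessimistic-pruning
#' confidence factor 0.25.
#'
#' @param min_leaf_size minimum number of training records a branch must
#'   receive for a split to be admissible (>= 1).
#' @param confidence_factor confidence factor \code{CF} of pessimistic
#'   pruning, in (0, 1); smaller values prune more aggressively.
#' @param max_depth optional depth bound (root = depth 0).
#' @param min_gain minimum information gain (bits) for a split to be
#'   considered.
#' @param gain_guard when TRUE (classic C4.5), only splits whose
#'   information gain reaches the mean gain of all candidate splits at
#'   the node compete on gain ratio; guards against split-information
#'   artifacts of many-valued attributes.
#' @param continuous_penalty when TRUE (C4.5 release 8 behaviour), the
#'   gain of a threshold split is charged the description cost of the
#'   threshold, \code{log2(#candidate thresholds) / n}; this strongly
#'   suppresses spurious splits on continuous noise.
#' @return a \code{tree_config} list.
#' @export
tree_config <- function(min_leaf_size = 2, confidence_factor = 0.25,
                        max_depth = Inf, min_gain = 1e-9,
                        gain_guard = TRUE, continuous_penalty = TRUE) {
  stopifnot(min_leaf_size >= 1, confidence_factor > 0, confidence_factor < 1,
            max_depth >= 1 || is.infinite(max_depth), min_gain >= 0)
  structure(list(min_leaf_size = min_leaf_size,
                 confidence_factor = confidence_factor,
                 max_depth = max_depth, min_gain = min_gain,
                 gain_guard = gain_guard,
                 continuous_penalty = continuous_penalty),
            class = "tree_config")
}

# two-class entropy in bits, vectorized over (a, b) count pairs
h2 <- function(a, b) {
  n <- a + b
  t <- function(k) ifelse(k > 0, -(k / n) * log2(k / n), 0)
  ifelse(n > 0, t(a) + t(b), 0)
}

# Pessimistic error rate: the Clopper-Pearson upper confidence bound on
# a binomial proportion (the rate p at which observing <= e errors in n
# trials has probability CF), floored at the observed rate so the
# estimate is never optimistic.  As CF -> 1 the bound degenerates to the
# observed rate and pruning (strict comparison) stops entirely.
pessimistic_rate <- function(e, n, cf) {
  if (n == 0) return(1)
  if (e >= n) return(1)
  max(e / n, stats::qbeta(1 - cf, e + 1, n - e))
}

#' Gain ratio of a candidate split
#'
#' Information gain of the binary partition induced by a condition
#' (records matching vs. not matching), divided by the split information;
#' both in bits.  Returns 0 when the gain is non-positive, and \code{NA}
#' (with a warning) for a degenerate split leaving one side empty --
#' such splits are excluded from candidacy during tree growth.
#'
#' @param split a \code{rule_condition}.
#' @param cohort labelled cohort (\code{class} column).
#' @return gain ratio in \code{[0, 1]}, or \code{NA} for a degenerate
#'   split.
#' @examples
#' co <- data.frame(x = c(1, 2, 3, 4), class = c("a", "a", "b", "b"))
#' gain_ratio(condition("x", "le", value = 2.5), co)   # 1
#' @export
gain_ratio <- function(split, cohort) {
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$class)) stop("gain_ratio: cohort has no class column")
  schema <- attr(cohort, "schema") %||% infer_schema(cohort)
  m <- condition_matches(split, cohort, schema)
  y <- factor(cohort$class)
  if (!any(m) || all(m)) {
    warning("degenerate split: one branch is empty")
    return(NA_real_)
  }
  tab <- table(m, y)
  gain_ratio_from_table(tab)$ratio
}

# tab: branches x classes count matrix
gain_ratio_from_table <- function(tab) {
  n <- sum(tab)
  total <- entropy_bits(colSums(tab))
  branch_n <- rowSums(tab)
  cond_h <- sum(branch_n / n *
                  apply(tab, 1, entropy_bits))
  gain <- total - cond_h
  si <- entropy_bits(branch_n)
  ratio <- if (gain <= 0 || si <= 0) 0 else gain / si
  list(gain = max(gain, 0), split_info = si, ratio = ratio)
}

#' Best threshold split on a continuous attribute
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted values; among candidates with positive information gain (and
#' both branches of at least \code{min_leaf_size} records) the split
#' maximizing the gain ratio is returned, ties broken toward the
#' smallest threshold.
#'
#' @param attribute attribute name.
#' @param cohort labelled cohort.
#' @param min_leaf_size minimum records per branch.
#' @return \code{list(condition, threshold, gain, gain_ratio)}, or
#'   \code{NULL} when no admissible split exists (e.g. constant
#'   attribute).
#' @export
best_continuous_split <- function(attribute, cohort, min_leaf_size = 1) {
  cohort <- as.data.frame(cohort)
  x <- as.numeric(cohort[[attribute]])
  y <- factor(cohort$class)
  s <- scan_continuous(x, as.integer(y), min_leaf_size)
  if (is.null(s)) return(NULL)
  list(condition = condition(attribute, "le", value = s$threshold),
       threshold = s$threshold, gain = s$gain, gain_ratio = s$ratio)
}

# vectorized scan over all midpoint thresholds; y in {1, 2}.  With
# penalty = TRUE, each candidate's gain is charged the threshold
# description cost log2(#candidates)/n before selection.
scan_continuous <- function(x, y, min_leaf_size, penalty = FALSE) {
  ok <- is.finite(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 * min_leaf_size) return(NULL)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  all_cuts <- which(xs[-n] < xs[-1])             # boundary after position i
  cut <- all_cuts[all_cuts >= min_leaf_size &
                    (n - all_cuts) >= min_leaf_size]
  if (length(cut) == 0) return(NULL)
  c1 <- cumsum(ys == 1)
  l1 <- c1[cut]; ln <- cut
  l2 <- ln - l1
  t1 <- c1[n]
  r1 <- t1 - l1; rn <- n - ln; r2 <- rn - r1
  total <- h2(t1, n - t1)
  gain <- total - (ln / n) * h2(l1, l2) - (rn / n) * h2(r1, r2)
  if (penalty) gain <- gain - log2(length(all_cuts)) / n
  si <- h2(ln, rn)
  ratio <- ifelse(gain > 0 & si > 0, gain / si, 0)
  keep <- which(gain > 0)
  if (length(keep) == 0) return(NULL)
  best <- keep[order(-ratio[keep], cut[keep])][1]
  i <- cut[best]
  list(threshold = (xs[i] + xs[i + 1]) / 2, gain = gain[best],
       ratio = ratio[best])
}

infer_schema <- function(df) {
  attrs <- list()
  for (nm in setdiff(names(df), "class")) {
    x <- df[[nm]]
    attrs[[nm]] <- if (is.numeric(x))
      list(name = nm, kind = "continuous", units = "",
           range = range(x, finite = TRUE))
    else list(name = nm,
              kind = if (is.ordered(x)) "ordinal" else
                if (nlevels(factor(x)) == 2) "binary" else "nominal",
              units = "", levels = levels(factor(x)))
  }
  cls <- levels(factor(df$class))
  structure(attrs,
            class_attribute = list(name = "class", levels = cls),
            class = "cohort_schema")
}

#' Fit a C4.5 decision tree
#'
#' Grows a decision tree by recursive gain-ratio splitting: continuous
#' attributes get binary midpoint-threshold splits and may be reused
#' deeper in the tree; categorical attributes split one branch per
#' observed level and are consumed once per path.  Growth stops on node
#' purity, the depth bound, or when no admissible split remains (split
#' admissibility requires positive gain, the optional mean-gain guard,
#' and \code{min_leaf_size} records in the branches).  Ties between
#' equal gain ratios go to the earlier attribute in schema order, then
#' the smaller threshold, making the fit deterministic.  Pessimistic
#' subtree-replacement pruning (confidence-bound comparison) is applied
#' unless \code{prune = FALSE}.
#'
#' @param formula model formula, e.g. \code{class ~ .}.
#' @param data labelled cohort data frame.
#' @param config a [tree_config()].
#' @param prune apply pessimistic pruning after growth.
#' @return an object of class \code{c45} with elements \code{tree}
#'   (nested node list), \code{config}, \code{levels}, \code{schema} and
#'   the training data (kept for rule simplification).
#' @seealso [as_ruleset()], [prune_tree()]
#' @examples
#' co <- generate_cohort(default_cohort_spec(200, 200), seed = 7)
#' fit <- c45(class ~ HbA1c + FPG, co, tree_config(max_depth = 3))
#' fit
#' @export
c45 <- function(formula, data, config = tree_config(), prune = TRUE) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data)
  y <- factor(stats::model.response(mf))
  X <- mf[-1]
  if (nrow(X) == 0) stop("c45: empty cohort")
  for (nm in names(X)) if (!is.numeric(X[[nm]])) X[[nm]] <- factor(X[[nm]])
  schema <- infer_schema(cbind(X, class = y))
  kinds <- vapply(schema, `[[`, "", "kind")
  root <- build_node(X, y, avail = names(X), kinds = kinds,
                     config = config, depth = 0)
  fit <- structure(list(tree = root, config = config, levels = levels(y),
                        schema = schema, data = cbind(X, class = y),
                        call = match.call()),
                   class = "c45")
  if (prune) fit <- prune_tree(fit)
  fit
}

make_leaf <- function(counts) {
  n <- sum(counts)
  cls <- names(counts)[which.max(counts)]   # tie -> first class level
  list(leaf = TRUE, class = cls, n = n, counts = counts,
       n_errors = n - max(counts))
}

build_node <- function(X, y, avail, kinds, config, depth) {
  counts <- table(y)
  n <- length(y)
  if (n == 0) stop("c45: empty node")
  if (length(unique(y[!is.na(y)])) <= 1 || depth >= config$max_depth ||
      n < 2 * config$min_leaf_size || length(avail) == 0)
    return(make_leaf(counts))

  # candidate best split per attribute
  cand <- list()
  for (a in avail) {
    if (kinds[[a]] == "continuous") {
      s <- scan_continuous(as.numeric(X[[a]]), as.integer(y),
                           config$min_leaf_size,
                           penalty = isTRUE(config$continuous_penalty))
      if (!is.null(s))
        cand[[a]] <- list(attr = a, kind = "continuous",
                          threshold = s$threshold, gain = s$gain,
                          ratio = s$ratio)
    } else {
      xa <- droplevels(factor(X[[a]]))
      if (nlevels(xa) < 2) next
      tab <- table(xa, y)
      if (sum(rowSums(tab) >= config$min_leaf_size) < 2) next
      g <- gain_ratio_from_table(tab)
      if (g$gain > 0)
        cand[[a]] <- list(attr = a, kind = "categorical",
                          branch_levels = levels(xa), gain = g$gain,
                          ratio = g$ratio)
    }
  }
  if (length(cand) == 0) return(make_leaf(counts))
  gains <- vapply(cand, `[[`, 0, "gain")
  admissible <- gains > config$min_gain
  if (config$gain_guard)
    admissible <- admissible & gains >= mean(gains) - 1e-12
  if (!any(admissible)) return(make_leaf(counts))
  cand <- cand[admissible]
  ratios <- vapply(cand, `[[`, 0, "ratio")
  # tie-break: max ratio, then schema (avail) order -- preserved because
  # cand is built in avail order and which.max takes the first maximum
  best <- cand[[which.max(ratios)]]

  if (best$kind == "continuous") {
    m <- as.numeric(X[[best$attr]]) <= best$threshold
    kids <- list(
      le = build_node(X[m, , drop = FALSE], y[m], avail, kinds, config,
                      depth + 1),
      gt = build_node(X[!m, , drop = FALSE], y[!m], avail, kinds, config,
                      depth + 1))
    list(leaf = FALSE, attr = best$attr, kind = "continuous",
         threshold = best$threshold, children = kids, n = n,
         counts = counts)
  } else {
    avail2 <- setdiff(avail, best$attr)   # nominal consumed once per path
    kids <- lapply(best$branch_levels, function(lv) {
      m <- as.character(X[[best$attr]]) == lv
      build_node(X[m, , drop = FALSE], y[m], avail2, kinds, config,
                 depth + 1)
    })
    names(kids) <- best$branch_levels
    list(leaf = FALSE, attr = best$attr, kind = "categorical",
         children = kids, n = n, counts = counts)
  }
}

n_leaves <- function(node) {
  if (node$leaf) return(1L)
  sum(vapply(node$children, n_leaves, 1L))
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(vapply(node$children, tree_depth, 1L))
}

#' Pessimistic pruning of a fitted tree
#'
#' Bottom-up subtree replacement: a subtree is replaced by its
#' majority-class leaf when the leaf's pessimistic error count (an upper
#' binomial confidence bound at the configured confidence factor,
#' floored at the observed rate and applied to the training counts)
#' falls below the sum of its leaves' pessimistic errors.  As the
#' confidence factor approaches 1 the bound collapses onto the observed
#' error counts, which a subtree never exceeds, so pruning stops
#' entirely.  Training accuracy never increases under
#' pruning, and the result is a topological contraction of the input
#' tree.
#'
#' @param fit a \code{c45} fit.
#' @param config optionally override the pruning configuration.
#' @return the pruned \code{c45} fit.
#' @export
prune_tree <- function(fit, config = fit$config) {
  fit$tree <- prune_node(fit$tree, config$confidence_factor)
  fit
}

prune_node <- function(node, cf) {
  if (node$leaf) return(node)
  node$children <- lapply(node$children, prune_node, cf = cf)
  sub_pe <- subtree_pessimistic_errors(node, cf)
  e_leaf <- node$n - max(node$counts)
  leaf_pe <- node$n * pessimistic_rate(e_leaf, node$n, cf)
  if (leaf_pe < sub_pe) make_leaf(node$counts) else node
}

subtree_pessimistic_errors <- function(node, cf) {
  if (node$leaf)
    return(node$n * pessimistic_rate(node$n_errors, node$n, cf))
  sum(vapply(node$children, subtree_pessimistic_errors, 0, cf = cf))
}

#' @export
predict.c45 <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  out <- rep(NA_character_, nrow(newdata))
  route <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    if (node$kind == "continuous") {
      m <- as.numeric(newdata[[node$attr]][idx]) <= node$threshold
      route(node$children$le, idx[m])
      route(node$children$gt, idx[!m])
    } else {
      v <- as.character(newdata[[node$attr]][idx])
      seen <- rep(FALSE, length(idx))
      for (lv in names(node$children)) {
        m <- !is.na(v) & v == lv
        seen <- seen | m
        route(node$children[[lv]], idx[m])
      }
      # level unseen at training time: fall back to the node majority
      if (any(!seen))
        out[idx[!seen]] <<- names(node$counts)[which.max(node$counts)]
    }
  }
  route(object$tree, seq_len(nrow(newdata)))
  factor(out, levels = object$levels)
}

#' Convert a fitted tree to an if-then rule set
#'
#' One rule per leaf: the conjunction of conditions along the
#' root-to-leaf path implies the leaf class.  Same-attribute bounds on a
#' path are tightened (e.g. \code{A <= 5} and \code{A <= 7} collapse to
#' \code{A <= 5}) and a lower+upper bound pair is emitted as a half-open
#' interval condition; both transformations preserve semantics, so the
#' unsimplified rules are mutually exclusive and jointly exhaustive over
#' the attribute space.
#'
#' With \code{simplify = TRUE} (the C4.5-rules post-processing step)
#' each rule greedily drops conditions whose removal does not increase
#' the rule's pessimistic error on the training cohort; rules are then
#' ordered by pessimistic error (most reliable first) and a
#' majority-class default rule is appended, so the set remains total
#' under first-match evaluation.
#'
#' @param fit a \code{c45} fit.
#' @param simplify apply condition-dropping simplification.
#' @param data training cohort for the simplification error estimates;
#'   defaults to the data stored in the fit.
#' @return a \code{ruleset}.
#' @export
as_ruleset <- function(fit, simplify = FALSE, data = fit$data) {
  paths <- list()
  walk <- function(node, conds) {
    if (node$leaf) {
      paths[[length(paths) + 1]] <<- list(conds = conds, class = node$class)
      return()
    }
    if (node$kind == "continuous") {
      walk(node$children$le,
           c(conds, list(condition(node$attr, "le", value = node$threshold))))
      walk(node$children$gt,
           c(conds, list(condition(node$attr, "gt", value = node$threshold))))
    } else {
      for (lv in names(node$children))
        walk(node$children[[lv]],
             c(conds, list(condition(node$attr, "eq", level = lv))))
    }
  }
  walk(fit$tree, list())
  rules <- lapply(seq_along(paths), function(i)
    rule(sprintf("R%d", i), tighten_conditions(paths[[i]]$conds),
         paths[[i]]$class))
  rs <- ruleset(rules, schema = fit$schema, note = "tree-derived rules")
  if (!simplify) return(rs)
  simplify_ruleset(rs, data, fit$config$confidence_factor)
}

#' @rdname as_ruleset
#' @export
tree_to_rules <- as_ruleset

# collapse redundant same-attribute bounds; pair lower+upper into intervals
tighten_conditions <- function(conds) {
  eqs <- Filter(function(cond) cond$op == "eq", conds)
  if (length(eqs) > 1)
    eqs <- eqs[!duplicated(vapply(eqs, function(cond)
      paste(cond$attribute, cond$level), ""))]
  num <- Filter(function(cond) cond$op != "eq", conds)
  out <- eqs
  attrs <- unique(vapply(num, `[[`, "", "attribute"))
  for (a in attrs) {
    ac <- Filter(function(cond) cond$attribute == a, num)
    ub <- suppressWarnings(min(vapply(
      Filter(function(cond) cond$op %in% c("le", "in"), ac),
      function(cond) cond$value %||% cond$high, 0)))
    lb <- suppressWarnings(max(vapply(
      Filter(function(cond) cond$op %in% c("gt", "in"), ac),
      function(cond) cond$value %||% cond$low, 0)))
    has_ub <- is.finite(ub); has_lb <- is.finite(lb)
    out <- c(out, list(
      if (has_ub && has_lb) condition(a, "in", low = lb, high = ub)
      else if (has_ub) condition(a, "le", value = ub)
      else condition(a, "gt", value = lb)))
  }
  out
}

simplify_ruleset <- function(rs, data, cf) {
  data <- as.data.frame(data)
  y <- as.character(data$class)
  simplified <- lapply(rs$rules, function(r) {
    conds <- r$conditions
    wrong <- y != r$consequent
    # per-condition match columns, so dropping a condition is a cheap
    # row-sum comparison rather than a re-evaluation of the conjunction
    M <- vapply(conds, condition_matches, logical(nrow(data)),
                data = data, schema = rs$schema)
    M <- matrix(M, nrow = nrow(data))
    pe_with <- function(keep) {
      m <- rowSums(M[, keep, drop = FALSE]) == length(keep)
      pessimistic_rate(sum(m & wrong), sum(m), cf)
    }
    keep <- seq_along(conds)
    pe <- pe_with(keep)
    repeat {
      if (length(keep) == 0) break
      trial <- vapply(seq_along(keep), function(j)
        pe_with(keep[-j]), 0)
      j <- which.min(trial)
      if (trial[j] <= pe + 1e-12) {
        keep <- keep[-j]
        pe <- trial[j]
      } else break
    }
    list(rule = rule(r$id, conds[keep], r$consequent), pe = pe)
  })
  pes <- vapply(simplified, `[[`, 0, "pe")
  ord <- order(pes)
  rules <- lapply(simplified[ord], `[[`, "rule")
  # drop rules made identical by simplification
  keys <- vapply(rules, function(r)
    paste(vapply(r$conditions, format_condition, ""), r$consequent,
          collapse = "|"), "")
  rules <- rules[!duplicated(keys)]
  maj <- names(which.max(table(y)))
  rules[[length(rules) + 1]] <- rule("default", list(), maj)
  for (i in seq_along(rules))
    rules[[i]]$id <- if (identical(rules[[i]]$id, "default")) "default"
                     else sprintf("R%d", i)
  out <- ruleset(rules, schema = rs$schema, note = "simplified tree rules")
  # discard rules shadowed into inactivity by the final ordering
  fired <- apply_rules(out, data)$rule
  live <- vapply(out$rules, function(r)
    r$id == "default" || r$id %in% fired, TRUE)
  out$rules <- out$rules[live]
  out
}

#' @export
print.c45 <- function(x, ...) {
  cat(sprintf("C4.5 tree: %d leaves, depth %d, trained on %d records\n",
              n_leaves(x$tree), tree_depth(x$tree), x$tree$n))
  print_node(x$tree, indent = "")
  invisible(x)
}

print_node <- function(node, indent) {
  if (node$leaf) {
    cat(sprintf("%s-> %s (n=%d, err=%d)\n", indent, node$class, node$n,
                node$n_errors))
    return()
  }
  if (node$kind == "continuous") {
    cat(sprintf("%s%s <= %g:\n", indent, node$attr, node$threshold))
    print_node(node$children$le, paste0(indent, "  "))
    cat(sprintf("%s%s > %g:\n", indent, node$attr, node$threshold))
    print_node(node$children$gt, paste0(indent, "  "))
  } else {
    for (lv in names(node$children)) {
      cat(sprintf("%s%s = %s:\n", indent, node$attr, lv))
      print_node(node$children[[lv]], paste0(indent, "  "))
    }
  }
}

#' Export a fitted tree as JSON (nested nodes with counts)
#' @param fit a \code{c45} fit.
#' @param path file path.
#' @export
write_tree_json <- function(fit, path) {
  to_list <- function(node) {
    if (node$leaf)
      return(list(leaf = TRUE, class = node$class, n = node$n,
                  errors = node$n_errors,
                  counts = as.list(as.integer(node$counts))))
    kids <- lapply(node$children, to_list)
    base <- list(leaf = FALSE, attr = node$attr, kind = node$kind,
                 n = node$n, children = kids)
    if (node$kind == "continuous") base$threshold <- node$threshold
    base
  }
  jsonlite::write_json(to_list(fit$tree), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
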