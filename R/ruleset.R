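#' Conditions, rules and rule sets
#'
#' An if-then diagnostic model is an ordered list of rules, each a
#' conjunction of conditions with a class consequent.  Conditions are one
#' of: \code{attr <= t}, \code{attr > t}, \code{attr in (low, high]}
#' (half-open interval), or \code{attr = level} for categorical
#' attributes.  A condition may also reference a level-indicator derived
#' from a nominal attribute (e.g. \code{Mexican-American = Yes} tests
#' \code{Race == "Mexican-American"}).
#'
#' @param attribute attribute (or level-indicator) name.
#' @param op one of \code{"le"} (\code{<=}), \code{"gt"} (\code{>}),
#'   \code{"in"} (interval) or \code{"eq"} (category equality).
#' @param value threshold for \code{le}/\code{gt}.
#' @param low,high interval bounds, interpreted as \code{(low, high]}.
#' @param level category level for \code{eq}.
#' @return \code{condition} returns a \code{rule_condition}; \code{rule} a
#'   \code{rule}; \code{ruleset} a \code{ruleset}.
#' @export
condition <- function(attribute, op, value = NULL, low = NULL, high = NULL,
                      level = NULL) {
  op <- match.arg(op, c("le", "gt", "in", "eq"))
  if (op %in% c("le", "gt") && (is.null(value) || !is.finite(value)))
    stop("condition: ops 'le'/'gt' need a finite threshold 'value'")
  if (op == "in") {
    if (is.null(low) || is.null(high) || !(low < high))
      stop("condition: op 'in' needs bounds with low < high")
  }
  if (op == "eq" && (is.null(level) || !nzchar(level)))
    stop("condition: op 'eq' needs a category 'level'")
  structure(list(attribute = attribute, op = op, value = value,
                 low = low, high = high, level = level),
            class = "rule_condition")
}

#' @param id rule label, e.g. \code{"R11"}.
#' @param conditions list of conditions (empty only for a default rule).
#' @param consequent predicted class label.
#' @rdname condition
#' @export
rule <- function(id, conditions, consequent) {
  stopifnot(is.list(conditions))
  structure(list(id = id, conditions = conditions, consequent = consequent),
            class = "rule")
}

#' @param rules list of rules, evaluated in order (first match wins).
#' @param schema attribute schema the rules are bound to.
#' @param note free-text provenance note.
#' @rdname condition
#' @export
ruleset <- function(rules, schema = nhanes_schema(), note = "") {
  stopifnot(all(vapply(rules, inherits, TRUE, "rule")))
  structure(list(rules = rules, schema = schema, note = note),
            class = "ruleset")
}

#' @export
length.ruleset <- function(x) length(x$rules)

#' Reference 15-rule prediabetes/diabetes model
#'
#' The published 15-rule model (R1--R15) discriminating prediabetes from
#' diabetes in the national health-survey cohort, shipped with the
#' package as a plain-text fixture and parsed on demand.  Interval
#' conditions are encoded half-open \code{(low, high]}, the only gap-free
#' reading consistent with the neighbouring \code{<=}/\code{>} rules; the
#' set partitions the in-range input space, so every in-range record
#' matches exactly one rule.  Notable cut-offs: UACR 6.1 and 71.00 mg/g
#' Cr (rules R6/R7 and R11/R12).
#'
#' @return A \code{ruleset} with 15 rules.
#' @examples
#' rs <- diabetes_rules()
#' extract_thresholds(rs, "UACR")   # 6.1, 71
#' @export
diabetes_rules <- function() {
  path <- system.file("extdata", "diabetes_rules.txt", package = "rerx",
                      mustWork = TRUE)
  rs <- parse_rules(paste(readLines(path, encoding = "UTF-8"),
                          collapse = "\n"))
  rs$note <- "reference 15-rule prediabetes/diabetes model"
  rs
}

# ---- evaluation ------------------------------------------------------------

# Logical match vector of one condition over a cohort data frame.
condition_matches <- function(cond, data, schema) {
  res <- resolve_attribute(schema, cond$attribute)
  if (is.null(res))
    stop(sprintf("unknown attribute '%s' in rule condition", cond$attribute))
  x <- data[[res$attr]]
  if (is.null(x))
    stop(sprintf("data lacks column '%s'", res$attr))
  if (!is.null(res$level)) {           # indicator attribute: = Yes / = No
    if (cond$op != "eq")
      stop(sprintf("indicator attribute '%s' only supports '='", cond$attribute))
    ind <- as.character(x) == res$level
    if (cond$level %in% c("Yes", "1")) return(ind)
    if (cond$level %in% c("No", "0")) return(!ind)
    stop(sprintf("indicator condition on '%s' must compare to Yes/No",
                 cond$attribute))
  }
  switch(cond$op,
    le = as.numeric(x) <= cond$value,
    gt = as.numeric(x) > cond$value,
    `in` = as.numeric(x) > cond$low & as.numeric(x) <= cond$high,
    eq = as.character(x) == cond$level)
}

rule_matches <- function(r, data, schema) {
  m <- rep(TRUE, nrow(data))
  for (cond in r$conditions) m <- m & condition_matches(cond, data, schema)
  m
}

#' Classify records with a rule set (first match wins)
#'
#' Evaluates the rules in listed order and returns, per record, the
#' consequent of the first rule whose conjunction is satisfied together
#' with that rule's id.  Records matched by no rule are reported
#' explicitly as uncovered (\code{NA} class, rule id
#' \code{"(uncovered)"}) -- never silently defaulted.
#'
#' @param rules a \code{ruleset}.
#' @param data a cohort data frame (one or more records).
#' @return \code{data.frame(class, rule)} with one row per record.
#' @examples
#' rs <- diabetes_rules()
#' rec <- generate_cohort(default_cohort_spec(10, 0), seed = 1)[1, ]
#' rec$HbA1c <- 7.0
#' apply_rules(rs, rec)    # diabetes via R15
#' @export
apply_rules <- function(rules, data) {
  stopifnot(inherits(rules, "ruleset"))
  data <- as.data.frame(data)
  n <- nrow(data)
  cls <- rep(NA_character_, n)
  rid <- rep("(uncovered)", n)
  open <- rep(TRUE, n)
  for (r in rules$rules) {
    if (!any(open)) break
    m <- open & rule_matches(r, data, rules$schema)
    cls[m] <- r$consequent
    rid[m] <- r$id
    open <- open & !m
  }
  data.frame(class = cls, rule = rid, stringsAsFactors = FALSE)
}

#' @export
predict.ruleset <- function(object, newdata, ...) {
  apply_rules(object, newdata)$class
}

#' Per-rule support and error on a labelled cohort
#'
#' Support is the fraction of the cohort covered by a rule under
#' first-match semantics; error is the fraction of its covered records
#' whose label differs from the rule's consequent (0 by convention for a
#' rule covering nothing).  The uncovered remainder, if any, is reported
#' in the \code{"uncovered"} attribute and by the print method.
#'
#' @param rules a \code{ruleset}.
#' @param cohort labelled cohort (must contain a \code{class} column).
#' @return \code{data.frame(rule, support, error, n_covered)} of class
#'   \code{rule_stats}.
#' @export
rule_stats <- function(rules, cohort) {
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0) stop("rule_stats: empty cohort")
  if (is.null(cohort$class)) stop("rule_stats: cohort has no class column")
  hit <- apply_rules(rules, cohort)
  n <- nrow(cohort)
  rows <- lapply(rules$rules, function(r) {
    cov <- hit$rule == r$id
    ncov <- sum(cov)
    err <- if (ncov == 0) 0 else
      mean(as.character(cohort$class[cov]) != r$consequent)
    data.frame(rule = r$id, support = ncov / n, error = err,
               n_covered = ncov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "uncovered") <- sum(hit$rule == "(uncovered)") / n
  class(out) <- c("rule_stats", "data.frame")
  out
}

#' @export
print.rule_stats <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  unc <- attr(x, "uncovered")
  if (!is.null(unc) && unc > 0)
    cat(sprintf("uncovered fraction: %.4f\n", unc))
  invisible(x)
}

#' Distinct numeric thresholds a rule set places on an attribute
#'
#' Collects every numeric boundary (thresholds of \code{<=}/\code{>}
#' conditions and both interval endpoints) mentioned for the attribute,
#' deduplicated and ascending.  This is the threshold-discovery query
#' used to read clinical cut-offs (such as the UACR values 6.1 and 71.00
#' mg/g Cr) off an extracted model; it is invariant under rule
#' reordering.
#'
#' @param rules a \code{ruleset}.
#' @param attribute a continuous attribute name.
#' @return sorted numeric vector (possibly empty).
#' @export
extract_thresholds <- function(rules, attribute) {
  schema <- rules$schema
  res <- resolve_attribute(schema, attribute)
  if (is.null(res) || !is.null(res$level) ||
      schema[[res$attr]]$kind != "continuous")
    stop(sprintf("extract_thresholds: unknown or non-continuous attribute '%s'",
                 attribute))
  th <- numeric(0)
  for (r in rules$rules) for (cond in r$conditions) {
    if (cond$attribute != attribute) next
    th <- c(th, switch(cond$op, le = cond$value, gt = cond$value,
                       `in` = c(cond$low, cond$high), eq = numeric(0)))
  }
  sort(unique(th))
}

# ---- text serialization ----------------------------------------------------

format_condition <- function(cond) {
  switch(cond$op,
    le = sprintf("%s <= %s", cond$attribute, format(cond$value, digits = 15)),
    gt = sprintf("%s > %s", cond$attribute, format(cond$value, digits = 15)),
    `in` = sprintf("%s in (%s, %s]", cond$attribute,
                   format(cond$low, digits = 15),
                   format(cond$high, digits = 15)),
    eq = sprintf("%s = %s", cond$attribute, cond$level))
}

#' Serialize / parse rule sets as human-readable text
#'
#' One rule per line in the grammar
#' \preformatted{[<id>:] IF <cond> (AND <cond>)* THEN <class>}
#' with condition operators \code{<=}, \code{>}, \code{in (a, b]} and
#' \code{= <level>}.  A default (condition-free) rule is written
#' \code{IF TRUE THEN <class>}.  Blank lines and lines starting with
#' \code{#} are ignored on parse.  \code{parse_rules(serialize_rules(x))}
#' reproduces \code{x} exactly.
#'
#' @param rules a \code{ruleset}.
#' @param text character scalar (or vector of lines).
#' @param schema schema to bind parsed rules to.
#' @return \code{serialize_rules}: a single string;
#'   \code{parse_rules}: a \code{ruleset}.
#' @examples
#' parse_rules("IF HbA1c > 6.4 THEN diabetes")
#' @export
serialize_rules <- function(rules) {
  lines <- vapply(rules$rules, function(r) {
    ifp <- if (length(r$conditions) == 0) "TRUE" else
      paste(vapply(r$conditions, format_condition, ""), collapse = " AND ")
    sprintf("%s: IF %s THEN %s", r$id, ifp, r$consequent)
  }, "")
  paste(lines, collapse = "\n")
}

#' @rdname serialize_rules
#' @export
parse_rules <- function(text, schema = nhanes_schema()) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rules <- list()
  auto <- 0
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line, regexec(
      "^(?:([^:]+):\\s*)?IF\\s+(.*)\\s+THEN\\s+(\\S+)\\s*$", line,
      perl = TRUE))[[1]]
    if (length(m) == 0)
      stop(sprintf("rule parse error at line %d, column 1: expected '[id:] IF ... THEN <class>'", i))
    id <- trimws(m[2])
    if (!nzchar(id)) { auto <- auto + 1; id <- sprintf("R%d", auto) }
    body <- m[3]
    consequent <- m[4]
    conds <- list()
    if (trimws(body) != "TRUE") {
      parts <- strsplit(body, "\\s+AND\\s+")[[1]]
      for (p in parts) {
        conds[[length(conds) + 1]] <- parse_condition(p, i,
          col = regexpr(p, line, fixed = TRUE)[1])
      }
    }
    rules[[length(rules) + 1]] <- rule(id, conds, consequent)
  }
  ruleset(rules, schema = schema)
}

parse_condition <- function(p, line, col) {
  p <- trimws(p)
  m <- regmatches(p, regexec(
    "^(.*?)\\s+in\\s+\\(\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*\\]$", p,
    perl = TRUE))[[1]]
  if (length(m) > 0)
    return(condition(trimws(m[2]), "in",
                     low = as.numeric(m[3]), high = as.numeric(m[4])))
  m <- regmatches(p, regexec("^(.*?)\\s*(<=|>|=)\\s*(.+)$", p,
                             perl = TRUE))[[1]]
  if (length(m) == 0)
    stop(sprintf("rule parse error at line %d, column %d: cannot parse condition '%s'",
                 line, max(col, 1), p))
  attr_ <- trimws(m[2]); op <- m[3]; rhs <- trimws(m[4])
  if (op == "=") return(condition(attr_, "eq", level = rhs))
  val <- suppressWarnings(as.numeric(rhs))
  if (is.na(val))
    stop(sprintf("rule parse error at line %d, column %d: non-numeric threshold '%s'",
                 line, max(col, 1), rhs))
  condition(attr_, if (op == "<=") "le" else "gt", value = val)
}

# ---- JSON serialization ----------------------------------------------------

#' Read / write rule sets as JSON
#'
#' Schema: \code{\{"note", "rules": [\{"id", "conditions":
#' [\{"attr", "op", "value" | "low"/"high" | "level"\}], "then"\}]\}}
#' with ops \code{"<="}, \code{">"}, \code{"in"}, \code{"="}.
#'
#' @param rules a \code{ruleset}.
#' @param path file path.
#' @param schema schema to bind parsed rules to.
#' @export
write_rules_json <- function(rules, path) {
  out <- list(note = rules$note,
    rules = lapply(rules$rules, function(r) list(
      id = r$id,
      conditions = lapply(r$conditions, function(cond) switch(cond$op,
        le = list(attr = cond$attribute, op = "<=", value = cond$value),
        gt = list(attr = cond$attribute, op = ">", value = cond$value),
        `in` = list(attr = cond$attribute, op = "in",
                    low = cond$low, high = cond$high),
        eq = list(attr = cond$attribute, op = "=", level = cond$level))),
      then = r$consequent)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rules_json
#' @export
read_rules_json <- function(path, schema = nhanes_schema()) {
  raw <- jsonlite::read_json(path)
  rules <- lapply(raw$rules, function(r) {
    conds <- lapply(r$conditions, function(cond) switch(cond$op,
      "<=" = condition(cond$attr, "le", value = as.numeric(cond$value)),
      ">"  = condition(cond$attr, "gt", value = as.numeric(cond$value)),
      "in" = condition(cond$attr, "in", low = as.numeric(cond$low),
                       high = as.numeric(cond$high)),
      "="  = condition(cond$attr, "eq", level = cond$level),
      stop(sprintf("unknown condition op '%s' in %s", cond$op, path))))
    rule(r$id, conds, r$then)
  })
  ruleset(rules, schema = schema, note = raw$note %||% "")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("Rule set: %d rule(s)", length(x$rules)))
  if (nzchar(x$note)) cat(" -- ", x$note, sep = "")
  cat("\n")
  cat(serialize_rules(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rule <- function(x, ...) {
  ifp <- if (length(x$conditions) == 0) "TRUE" else
    paste(vapply(x$conditions, format_condition, ""), collapse = " AND ")
  sprintf("%s: IF %s THEN %s", x$id, ifp, x$consequent)
}

#' @export
print.rule <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
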