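#' Generate a synthetic diabetes/prediabetes cohort
#'
#' Simulates a labelled cohort from a class-conditional specification
#' (see [default_cohort_spec()]).  Class labels are fixed first (exactly
#' \code{n_diabetes} then \code{n_prediabetes} records -- counts are exact
#' by construction, not binomially sampled); attributes are then drawn
#' independently within class from the specified normal, log-normal or
#' categorical distributions, and continuous values are clipped to the
#' schema ranges.  Identical \code{(spec, seed)} pairs yield identical
#' cohorts.
#'
#' Because published summaries are per-attribute marginals, attributes
#' are independent within class; and because labels follow the sampled
#' class, a record's label need not agree with a re-application of the
#' glycaemic criteria (see [ada_label()]) -- self-reported diagnosed
#' diabetes admits sub-threshold HbA1c.
#'
#' @param spec a \code{cohort_spec}.
#' @param seed integer seed; every draw derives from it.
#' @return A \code{data.frame} with one column per schema attribute plus
#'   a \code{class} factor, carrying the schema as attribute
#'   \code{"schema"} and S3 class \code{c("cohort", "data.frame")}.
#' @examples
#' co <- generate_cohort(default_cohort_spec(), seed = 1)
#' table(co$class)     # 942 diabetes, 524 prediabetes
#' @export
generate_cohort <- function(spec, seed) {
  validate_cohort_spec(spec)
  schema <- spec$schema
  classes <- schema_class_levels(schema)
  counts <- c(spec$n_diabetes, spec$n_prediabetes)
  names(counts) <- classes

  with_seed(seed, {
    blocks <- lapply(classes, function(cls) {
      n <- counts[[cls]]
      cols <- lapply(schema, function(a)
        draw_attribute(a, spec$params[[cls]][[a$name]], n))
      names(cols) <- names(schema)
      cols$class <- rep(cls, n)
      as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
  })
  rownames(out) <- NULL
  as_cohort(out, schema)
}

draw_attribute <- function(a, p, n) {
  if (n == 0) {
    if (a$kind == "continuous") return(numeric(0))
    return(character(0))
  }
  if (a$kind == "continuous") {
    x <- switch(p$dist,
      normal    = stats::rnorm(n, p$mean, p$sd),
      lognormal = stats::rlnorm(n, meanlog = log(p$median), sdlog = p$sdlog))
    pmin(pmax(x, a$range[1]), a$range[2])
  } else {
    sample(names(p$probs), n, replace = TRUE, prob = p$probs)
  }
}

as_cohort <- function(df, schema) {
  for (a in schema) {
    if (a$kind == "continuous") {
      df[[a$name]] <- as.numeric(df[[a$name]])
    } else {
      df[[a$name]] <- factor(df[[a$name]], levels = a$levels,
                             ordered = a$kind == "ordinal")
    }
  }
  if ("class" %in% names(df))
    df$class <- factor(as.character(df$class),
                       levels = schema_class_levels(schema))
  attr(df, "schema") <- schema
  class(df) <- c("cohort", "data.frame")
  df
}

cohort_schema <- function(cohort) attr(cohort, "schema") %||% nhanes_schema()

#' Glycaemic classification by ADA criteria
#'
#' Applies the standard thresholds: diabetes when FPG >= 126 mg/dL or
#' HbA1c >= 6.5%; otherwise prediabetes when FPG is 100--125 mg/dL
#' (impaired fasting glucose) or HbA1c is 5.7--6.4%; otherwise
#' \code{"neither"}.  Vectorized.
#'
#' @param fpg fasting plasma glucose, mg/dL (positive).
#' @param hba1c glycated haemoglobin, percent (positive).
#' @return character vector in \code{\{"diabetes", "prediabetes",
#'   "neither"\}}.
#' @examples
#' ada_label(126, 5.0)   # "diabetes"
#' ada_label(110, 5.5)   # "prediabetes"
#' ada_label(99, 5.6)    # "neither"
#' @export
ada_label <- function(fpg, hba1c) {
  if (any(!is.finite(fpg)) || any(!is.finite(hba1c)) ||
      any(fpg <= 0) || any(hba1c <= 0))
    stop("ada_label: fpg and hba1c must be positive and finite")
  out <- rep("neither", length(fpg))
  pre <- (fpg >= 100 & fpg <= 125) | (hba1c >= 5.7 & hba1c <= 6.4)
  dia <- fpg >= 126 | hba1c >= 6.5
  out[pre] <- "prediabetes"
  out[dia] <- "diabetes"
  out
}

#' Write / read a cohort as CSV
#'
#' One header row of attribute names, one record per row, class column
#' \code{class} with values \code{diabetes}/\code{prediabetes}, UTF-8,
#' \code{.} decimal separator.  The round trip is lossless for categories
#' and lossless to well below 1e-9 for continuous values.
#'
#' On read, columns are checked against the schema: missing columns are
#' an error (listing them); missing predictor cells are an error unless
#' \code{drop_incomplete = TRUE}, which drops those rows; continuous
#' values outside the schema range produce a warning but are retained.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @param schema attribute schema; default [nhanes_schema()].
#' @param drop_incomplete drop rows with missing predictor cells instead
#'   of erroring.
#' @return \code{read_cohort} returns a cohort; \code{write_cohort}
#'   returns \code{path} invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  cont <- continuous_attrs(cohort_schema(cohort))
  for (nm in cont) df[[nm]] <- format(df[[nm]], digits = 15, trim = TRUE,
                                      scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema = nhanes_schema(),
                        drop_incomplete = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  want <- c(names(schema), "class")
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0)
    stop("cohort file is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[intersect(want, names(df))]

  pred_na <- rowSums(is.na(df[names(schema)])) > 0
  if (any(pred_na)) {
    if (drop_incomplete) df <- df[!pred_na, , drop = FALSE]
    else stop(sprintf("cohort file has %d row(s) with missing predictor cells; use drop_incomplete = TRUE to drop them",
                      sum(pred_na)))
  }

  bad_levels <- character(0)
  for (a in schema) {
    if (a$kind != "continuous") {
      vals <- unique(df[[a$name]])
      if (!all(vals %in% a$levels)) bad_levels <- c(bad_levels, a$name)
    }
  }
  if (length(bad_levels) > 0)
    stop("cohort file has unknown category levels in columns: ",
         paste(bad_levels, collapse = ", "))

  for (a in schema) {
    if (a$kind == "continuous") {
      x <- df[[a$name]]
      out_rng <- sum(x < a$range[1] | x > a$range[2], na.rm = TRUE)
      if (out_rng > 0)
        warning(sprintf("column '%s': %d value(s) outside range [%g, %g]; retained",
                        a$name, out_rng, a$range[1], a$range[2]))
    }
  }
  if ("class" %in% names(df)) {
    bad <- setdiff(unique(stats::na.omit(df$class)),
                   schema_class_levels(schema))
    if (length(bad) > 0)
      stop("cohort file has unknown class labels: ", paste(bad, collapse = ", "))
  }
  as_cohort(df, schema)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d records", nrow(x)))
  if ("class" %in% names(x)) {
    tb <- table(x$class)
    cat(" (", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
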