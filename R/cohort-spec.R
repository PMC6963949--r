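#' Default class-conditional generative specification
#'
#' Returns the generative parameters used to simulate NHANES-style
#' diabetes/prediabetes cohorts: class sizes 942 (diabetes) and 524
#' (prediabetes) and, per class and attribute, either a normal
#' distribution (printed mean and SD) for near-symmetric continuous
#' measurements, a log-normal (printed median plus a log-scale SD) for the
#' right-skewed ones (UACR, FPG, insulin, alcohol, triglycerides), or a
#' category-probability vector for the categorical attributes.  Category
#' percentages are renormalized to sum to one.  Continuous draws are
#' clipped to the schema ranges by the generator.
#'
#' Log-scale SDs are not published; defaults are 0.8 for UACR, 0.25 for
#' FPG and insulin, and 0.5 for triglycerides and alcohol.  Triglycerides
#' are published as mean (SD), so their log-normal location is chosen to
#' reproduce the printed mean (median = mean / exp(sdlog^2 / 2)).
#'
#' @param n_diabetes,n_prediabetes class sizes; defaults are the study
#'   cohort sizes (942 and 524).
#' @return An object of class \code{cohort_spec}: class sizes, schema and
#'   a \code{params[[class]][[attribute]]} table of distribution
#'   descriptors.
#' @seealso [generate_cohort()], [nhanes_schema()]
#' @examples
#' spec <- default_cohort_spec()
#' spec$params$diabetes$HbA1c     # normal, mean 7.38, sd 1.81
#' @export
default_cohort_spec <- function(n_diabetes = 942, n_prediabetes = 524) {
  norm_ <- function(mean, sd) list(dist = "normal", mean = mean, sd = sd)
  lnorm_ <- function(median, sdlog)
    list(dist = "lognormal", median = median, sdlog = sdlog)
  lnorm_mean <- function(mean, sdlog)   # location set from a printed mean
    list(dist = "lognormal", median = mean / exp(sdlog^2 / 2), sdlog = sdlog)
  cat_ <- function(...) {
    p <- c(...)
    list(dist = "categorical", probs = p / sum(p))
  }

  diabetes <- list(
    Age = norm_(60.01, 13.54),
    Sex = cat_(Female = 49.25, Male = 50.74),
    Race = cat_("Mexican-American" = 21.54, "Other Hispanic" = 9.235,
                "Non-Hispanic White" = 38.85, "Non-Hispanic Black" = 23.03,
                "Other race" = 7.32),
    SBP = norm_(130.57, 20.15),
    DBP = norm_(68.15, 14.99),
    Waist = norm_(107.73, 15.73),
    BMI = norm_(31.74, 6.93),
    TotalChol = norm_(183.31, 40.37),
    UACR = lnorm_(14.85, 0.8),
    HbA1c = norm_(7.38, 1.81),
    Tobacco = cat_("not at all" = 83.43, "some days" = 2.22,
                   "every day" = 14.33),
    Alcohol = lnorm_(1, 0.5),
    Exercise = cat_(No = 73.35, Yes = 26.64),
    Triglycerides = lnorm_mean(145.92, 0.5),
    LDL = norm_(104.18, 34.82),
    HDL = norm_(49.93, 13.63),
    FPG = lnorm_(139.8, 0.25),
    Insulin = lnorm_(12.74, 0.25),
    Bilirubin = norm_(0.72, 0.28)
  )

  # The published prediabetes race row carries a stray duplicate
  # "Hispanic" entry; its mass is folded into "Other Hispanic" and the
  # vector renormalized.
  prediabetes <- list(
    Age = norm_(55.04, 15.79),
    Sex = cat_(Female = 54.19, Male = 45.80),
    Race = cat_("Mexican-American" = 13.74, "Other Hispanic" = 6.87 + 9.235,
                "Non-Hispanic White" = 51.33, "Non-Hispanic Black" = 18.51,
                "Other race" = 9.54),
    SBP = norm_(125.47, 18.10),
    DBP = norm_(69.18, 13.14),
    Waist = norm_(104.66, 15.75),
    BMI = norm_(30.95, 7.05),
    TotalChol = norm_(198.19, 40.73),
    UACR = lnorm_(8.85, 0.8),
    HbA1c = norm_(5.92, 1.05),
    Tobacco = cat_("not at all" = 83.20, "some days" = 1.90,
                   "every day" = 14.88),
    Alcohol = lnorm_(1, 0.5),
    Exercise = cat_(No = 69.65, Yes = 30.34),
    Triglycerides = lnorm_mean(134.76, 0.5),
    LDL = norm_(118.79, 36.29),
    HDL = norm_(52.47, 14.88),
    FPG = lnorm_(108.0, 0.25),
    Insulin = lnorm_(12.1, 0.25),
    Bilirubin = norm_(0.730, 0.28)
  )

  spec <- structure(
    list(n_diabetes = n_diabetes, n_prediabetes = n_prediabetes,
         params = list(diabetes = diabetes, prediabetes = prediabetes),
         schema = nhanes_schema()),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks counts, distribution parameters and probability vectors; stops
#' with a message naming the offending field.
#' @param spec a \code{cohort_spec}.
#' @return \code{spec}, invisibly, if valid.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("not a cohort_spec object")
  for (f in c("n_diabetes", "n_prediabetes")) {
    n <- spec[[f]]
    if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != round(n))
      stop(sprintf("invalid cohort spec: '%s' must be a non-negative integer", f))
  }
  schema <- spec$schema
  for (cls in schema_class_levels(schema)) {
    pars <- spec$params[[cls]]
    if (is.null(pars))
      stop(sprintf("invalid cohort spec: missing parameters for class '%s'", cls))
    for (a in schema) {
      p <- pars[[a$name]]
      field <- sprintf("params$%s$%s", cls, a$name)
      if (is.null(p))
        stop(sprintf("invalid cohort spec: missing '%s'", field))
      if (a$kind == "continuous") {
        if (p$dist == "normal") {
          if (!is.finite(p$sd) || p$sd <= 0)
            stop(sprintf("invalid cohort spec: '%s' sd must be > 0", field))
        } else if (p$dist == "lognormal") {
          if (!is.finite(p$median) || p$median <= 0)
            stop(sprintf("invalid cohort spec: '%s' median must be > 0", field))
          if (!is.finite(p$sdlog) || p$sdlog <= 0)
            stop(sprintf("invalid cohort spec: '%s' sdlog must be > 0", field))
        } else stop(sprintf("invalid cohort spec: '%s' unknown distribution '%s'",
                            field, p$dist))
      } else {
        if (p$dist != "categorical")
          stop(sprintf("invalid cohort spec: '%s' must be categorical", field))
        pr <- p$probs
        if (length(pr) != length(a$levels) ||
            !setequal(names(pr), a$levels))
          stop(sprintf("invalid cohort spec: '%s' probabilities must be named by levels %s",
                       field, paste(a$levels, collapse = ", ")))
        if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
          stop(sprintf("invalid cohort spec: '%s' probabilities must be non-negative and sum to 1",
                       field))
      }
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d diabetes + %d prediabetes records\n",
              x$n_diabetes, x$n_prediabetes))
  cat("Class-conditional distributions (diabetes | prediabetes):\n")
  for (a in x$schema) {
    fmt <- function(p) switch(p$dist,
      normal      = sprintf("N(%.4g, %.3g)", p$mean, p$sd),
      lognormal   = sprintf("logN(med %.4g, sdlog %.3g)", p$median, p$sdlog),
      categorical = paste(sprintf("%s %.1f%%", names(p$probs),
                                  100 * p$probs), collapse = ", "))
    cat(sprintf("  %-14s %s | %s\n", a$name,
                fmt(x$params$diabetes[[a$name]]),
                fmt(x$params$prediabetes[[a$name]])))
  }
  invisible(x)
}

#' Read / write a cohort specification as JSON
#'
#' @param spec a \code{cohort_spec}.
#' @param path file path.
#' @return \code{read_cohort_spec} returns a validated \code{cohort_spec};
#'   \code{write_cohort_spec} returns \code{path} invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  out <- list(n_diabetes = spec$n_diabetes, n_prediabetes = spec$n_prediabetes,
              params = lapply(spec$params, function(cls)
                lapply(cls, function(p) {
                  if (p$dist == "categorical")
                    list(dist = "categorical", probs = as.list(p$probs))
                  else p
                })))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- jsonlite::read_json(path)
  schema <- nhanes_schema()
  params <- lapply(raw$params, function(cls)
    lapply(cls, function(p) {
      if (p$dist == "categorical")
        list(dist = "categorical", probs = unlist(p$probs))
      else lapply(p, function(v) if (is.numeric(v)) as.numeric(v) else v)
    }))
  spec <- structure(list(n_diabetes = as.integer(raw$n_diabetes),
                         n_prediabetes = as.integer(raw$n_prediabetes),
                         params = params, schema = schema),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}
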