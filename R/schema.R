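#' Attribute schema for the health-survey diabetes cohort
#'
#' The default schema describes the 19 predictor attributes of the
#' national health-survey (NHANES-style) diabetes dataset used throughout
#' the package -- 2 binary, 1 nominal race/ethnicity with 5 levels,
#' 1 ordered tobacco-use attribute and 15 continuous laboratory or
#' anthropometric measurements -- plus the binary class attribute with
#' levels \code{diabetes} and \code{prediabetes}.
#'
#' Continuous attributes carry an allowed \code{range} (values are clipped
#' to it on generation and checked with a warning on read); categorical
#' attributes carry their level sets.  Tobacco use is modelled as an
#' ordered factor (not at all < some days < every day).
#'
#' @return An object of class \code{cohort_schema}: a named list of
#'   attribute descriptors, each with fields \code{name}, \code{kind}
#'   (\code{"continuous"}, \code{"binary"}, \code{"nominal"} or
#'   \code{"ordinal"}), \code{units}, and either \code{range} (continuous)
#'   or \code{levels} (categorical).  The class attribute is stored in the
#'   \code{class_attribute} attribute of the list.
#' @examples
#' sch <- nhanes_schema()
#' length(sch)                # 19 predictors
#' sch$HbA1c$range            # 3.5 to 17.5 percent
#' @export
nhanes_schema <- function() {
  cont <- function(name, units, lo, hi)
    list(name = name, kind = "continuous", units = units, range = c(lo, hi))
  cat_ <- function(name, kind, levels, units = "")
    list(name = name, kind = kind, units = units, levels = levels)

  attrs <- list(
    cont("Age", "years", 20, 80),
    cat_("Sex", "binary", c("Female", "Male")),
    cat_("Race", "nominal", c("Mexican-American", "Other Hispanic",
                              "Non-Hispanic White", "Non-Hispanic Black",
                              "Other race")),
    cont("SBP", "mmHg", 62, 228),
    cont("DBP", "mmHg", 0, 118),
    cont("Waist", "cm", 40.2, 177.9),
    cont("BMI", "kg/m^2", 12.1, 82.9),
    cont("TotalChol", "mg/dL", 69, 813),
    cont("UACR", "mg/g Cr", 0.21, 9600),
    cont("HbA1c", "%", 3.5, 17.5),
    cat_("Tobacco", "ordinal", c("not at all", "some days", "every day")),
    cont("Alcohol", "drinks/day", 1, 25),
    cat_("Exercise", "binary", c("No", "Yes")),
    cont("Triglycerides", "mg/dL", 13, 4233),
    cont("LDL", "mg/dL", 14, 375),
    cont("HDL", "mg/dL", 8, 138),
    cont("FPG", "mg/dL", 51, 421),
    cont("Insulin", "uU/mL", 0.14, 682.48),
    cont("Bilirubin", "mg/dL", 0.1, 7.1)
  )
  names(attrs) <- vapply(attrs, `[[`, "", "name")
  structure(attrs,
            class_attribute = list(name = "class",
                                   levels = c("diabetes", "prediabetes")),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cls <- attr(x, "class_attribute")
  cat(sprintf("Cohort schema: %d predictor attributes + class {%s}\n",
              length(x), paste(cls$levels, collapse = ", ")))
  for (a in x) {
    rng <- if (a$kind == "continuous")
      sprintf("[%g, %g] %s", a$range[1], a$range[2], a$units)
    else paste(a$levels, collapse = " | ")
    cat(sprintf("  %-14s %-10s %s\n", a$name, a$kind, rng))
  }
  invisible(x)
}

schema_class_levels <- function(schema) attr(schema, "class_attribute")$levels

continuous_attrs <- function(schema)
  names(schema)[vapply(schema, function(a) a$kind == "continuous", TRUE)]

categorical_attrs <- function(schema)
  names(schema)[vapply(schema, function(a) a$kind != "continuous", TRUE)]

#' Resolve an attribute name that may be a level-indicator
#'
#' Rule conditions may reference indicator attributes derived from a
#' nominal attribute's levels (e.g. \code{"Mexican-American"} or
#' \code{"Non-Hispanic Black"}, which are levels of \code{Race}).  Returns
#' either \code{list(attr = name)} for a real attribute or
#' \code{list(attr = parent, level = level)} for an indicator, or NULL.
#' @noRd
resolve_attribute <- function(schema, name) {
  if (name %in% names(schema)) return(list(attr = name))
  for (a in schema) {
    if (a$kind != "continuous" && name %in% a$levels)
      return(list(attr = a$name, level = name))
  }
  NULL
}
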