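# Severity grading: map label endpoints + regulatory flags to the
# three-level DILI outcome (severe / less-severe / none).

#' Severity levels
#'
#' Ordered factor levels of the three-group DILI outcome.
#'
#' @return `c("none", "less_severe", "severe")`, lowest first.
#' @export
severity_levels <- function() c("none", "less_severe", "severe")

#' Grade one drug's DILI severity
#'
#' A drug is `severe` if its label reports fatality, liver failure or
#' liver transplantation, or if it carries a Hy's-law case, a black-box
#' warning or a market withdrawal; `less_severe` if it reports
#' hepatitis, hepatomegaly, jaundice or abnormal liver biomarkers but
#' none of the severe criteria; `none` otherwise. Severe criteria
#' dominate: adding endpoints can never lower the grade.
#'
#' @param endpoints Character vector of endpoint tokens for one drug
#'   (subset of [endpoint_vocabulary()]).
#' @param black_box,withdrawn,hys_law Logical regulatory flags.
#' @return One of `"severe"`, `"less_severe"`, `"none"`.
#' @examples
#' grade_severity("fatality")                    # "severe"
#' grade_severity(c("jaundice", "liver_failure")) # "severe"
#' grade_severity(character(0))                  # "none"
#' @export
grade_severity <- function(endpoints, black_box = FALSE, withdrawn = FALSE,
                           hys_law = FALSE) {
  unknown <- setdiff(endpoints, endpoint_vocabulary())
  if (length(unknown))
    .stop_schema(sprintf("unknown endpoint token: %s",
                         paste(unknown, collapse = ", ")))
  if (any(endpoints %in% severe_endpoints()) ||
      isTRUE(black_box) || isTRUE(withdrawn) || isTRUE(hys_law))
    return("severe")
  if (any(endpoints %in% less_severe_endpoints()))
    return("less_severe")
  "none"
}

#' Grade every drug in a catalog
#'
#' Appends a `severity` factor column (levels `none < less_severe <
#' severe`) computed by [grade_severity()] from the endpoint and flag
#' columns.
#'
#' @param catalog A `dili_catalog`.
#' @return The catalog with a `severity` column.
#' @export
grade_catalog <- function(catalog) {
  unknown <- setdiff(unique(unlist(catalog$endpoints, use.names = FALSE)),
                     endpoint_vocabulary())
  if (length(unknown))
    .stop_schema(sprintf("unknown endpoint token: %s",
                         paste(unknown, collapse = ", ")))
  has_severe <- vapply(catalog$endpoints,
                       function(e) any(e %in% severe_endpoints()), logical(1))
  has_less <- vapply(catalog$endpoints,
                     function(e) any(e %in% less_severe_endpoints()), logical(1))
  sev <- ifelse(has_severe | catalog$black_box | catalog$withdrawn |
                  catalog$hys_law, "severe",
                ifelse(has_less, "less_severe", "none"))
  catalog$severity <- factor(sev, levels = severity_levels(), ordered = TRUE)
  catalog
}

#' Severity group counts
#'
#' @param catalog A `dili_catalog` (graded on the fly if it has no
#'   `severity` column).
#' @return Named integer vector `c(severe, less_severe, none)`; the
#'   three counts sum to the number of drugs.
#' @export
summarize_severity <- function(catalog) {
  if (is.null(catalog$severity)) catalog <- grade_catalog(catalog)
  tab <- table(factor(catalog$severity, levels = severity_levels()))
  c(severe = unname(tab[["severe"]]),
    less_severe = unname(tab[["less_severe"]]),
    none = unname(tab[["none"]]))
}
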