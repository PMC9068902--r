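# Threshold-conjunction risk rules over drug properties (MW, LogP,
# DDD, LM): predicate evaluation, rule enumeration, 2x2 evaluation
# against DILI outcomes, and ranking.

.rule_properties <- c("MW", "LOGP", "DDD", "LM")
.property_columns <- c(MW = "mw", LOGP = "logp", DDD = "ddd", LM = "lm_percent")
.property_display <- c(MW = "MW", LOGP = "LogP", DDD = "DDD", LM = "LM")

#' Define a threshold predicate on one drug property
#'
#' @param property One of `"MW"` (Da), `"LOGP"`, `"DDD"` (mg/day),
#'   `"LM"` (percent).
#' @param kind `"ge"` (value >= bound), `"lt"` (value < bound) or
#'   `"interval"` (low <= value < high, half-open).
#' @param bounds One bound for `ge`/`lt`, two (low < high) for
#'   `interval`.
#' @return A `threshold_predicate` object with a canonical `label`.
#' @examples
#' threshold_predicate("MW", "interval", c(400, 600))
#' threshold_predicate("LOGP", "ge", 3)
#' @export
threshold_predicate <- function(property = c("MW", "LOGP", "DDD", "LM"),
                                kind = c("ge", "lt", "interval"),
                                bounds) {
  property <- match.arg(property)
  kind <- match.arg(kind)
  bounds <- as.numeric(bounds)
  if (kind == "interval") {
    if (length(bounds) != 2L || !(bounds[1] < bounds[2]))
      stop("interval predicates need bounds low < high")
  } else if (length(bounds) != 1L) {
    stop("ge/lt predicates take a single bound")
  }
  disp <- .property_display[[property]]
  unit <- if (property == "LM") "%" else ""
  label <- switch(kind,
    ge = sprintf("%s >= %s%s", disp, format(bounds[1]), unit),
    lt = sprintf("%s < %s%s", disp, format(bounds[1]), unit),
    interval = sprintf("%s <= %s < %s", format(bounds[1]), disp,
                       format(bounds[2])))
  structure(list(property = property, kind = kind, bounds = bounds,
                 label = label),
            class = "threshold_predicate")
}

#' The canonical four-predicate library
#'
#' The literature-derived thresholds behind the rule of four:
#' 400 <= MW < 600 Da, LogP >= 3, DDD >= 100 mg/day, LM >= 50%.
#'
#' @return Named list of four `threshold_predicate`s.
#' @export
canonical_predicates <- function() {
  list(MW = threshold_predicate("MW", "interval", c(400, 600)),
       LOGP = threshold_predicate("LOGP", "ge", 3),
       DDD = threshold_predicate("DDD", "ge", 100),
       LM = threshold_predicate("LM", "ge", 50))
}

#' Evaluate a predicate against property values
#'
#' @param values Numeric vector of property values (`NA` = missing).
#' @param predicate A `threshold_predicate`.
#' @param missing_policy `"negative"` (missing value fails the
#'   predicate, the default) or `"exclude"` (missing value propagates
#'   `NA`, marking the record for exclusion).
#' @return Logical vector; `NA` only under `"exclude"`.
#' @export
evaluate_predicate <- function(values, predicate,
                               missing_policy = c("negative", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  out <- switch(predicate$kind,
    ge = values >= predicate$bounds[1],
    lt = values < predicate$bounds[1],
    interval = values >= predicate$bounds[1] & values < predicate$bounds[2])
  if (missing_policy == "negative") out[is.na(out)] <- FALSE
  out
}

#' Build a risk rule from predicates
#'
#' A rule is a conjunction of at most one predicate per property. Its
#' label joins the predicate labels with `" and "` in the fixed
#' property order MW, LogP, DDD, LM, so labels are deterministic.
#'
#' @param predicates List of `threshold_predicate`s.
#' @return A `risk_rule` object.
#' @export
risk_rule <- function(predicates) {
  if (length(predicates) == 0L) stop("a rule needs at least one predicate")
  props <- vapply(predicates, `[[`, character(1), "property")
  if (anyDuplicated(props))
    stop("at most one predicate per property in a rule")
  ord <- order(match(props, .rule_properties))
  predicates <- predicates[ord]
  label <- paste(vapply(predicates, `[[`, character(1), "label"),
                 collapse = " and ")
  structure(list(predicates = predicates, label = label),
            class = "risk_rule")
}

#' @export
print.risk_rule <- function(x, ...) {
  cat("<risk_rule>", x$label, "\n")
  invisible(x)
}

#' Enumerate all non-empty predicate conjunctions
#'
#' Builds all 2^k - 1 rules from a k-predicate library, ordered by rule
#' size then canonical label.
#'
#' @param library List of `threshold_predicate`s, one per property.
#' @return List of `risk_rule`s.
#' @export
enumerate_rules <- function(library = canonical_predicates()) {
  if (length(library) == 0L) stop("empty predicate library")
  props <- vapply(library, `[[`, character(1), "property")
  if (anyDuplicated(props))
    stop("at most one predicate per property in the library")
  k <- length(library)
  rules <- list()
  for (mask in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    rules[[length(rules) + 1L]] <- risk_rule(library[idx])
  }
  sizes <- vapply(rules, function(r) length(r$predicates), integer(1))
  labels <- vapply(rules, `[[`, character(1), "label")
  rules[order(sizes, labels)]
}

#' Rule exposure indicator over a catalog
#'
#' @param catalog A `dili_catalog`.
#' @param rule A `risk_rule`.
#' @param missing_policy See [evaluate_predicate()]; under
#'   `"exclude"`, a record with any required property missing gets `NA`.
#' @return Logical vector along the catalog rows.
#' @export
rule_exposure <- function(catalog, rule,
                          missing_policy = c("negative", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  out <- rep(TRUE, nrow(catalog))
  for (pred in rule$predicates) {
    vals <- catalog[[.property_columns[[pred$property]]]]
    out <- out & evaluate_predicate(vals, pred, missing_policy)
  }
  out
}

#' Evaluate one risk rule against a DILI outcome
#'
#' Builds the 2x2 table (exposed = drugs satisfying every predicate of
#' the rule; outcome per `outcome`) over the evaluation cohort and
#' returns its association statistics. By default kinase inhibitors
#' (ATC `L01XE`) are excluded from the cohort, reflecting a design in
#' which the rule is derived from the KI class and validated on the
#' remaining drugs; set `include_kis = TRUE` to keep them.
#'
#' @param catalog A `dili_catalog` (graded on the fly if needed).
#' @param rule A `risk_rule`.
#' @param outcome `"dili"` or `"severe"`; see [outcome_arms()].
#' @param missing_policy `"negative"` keeps drugs with missing
#'   properties in the cohort as rule-negative (so every rule shares
#'   one denominator); `"exclude"` drops them.
#' @param include_kis Keep kinase inhibitors in the cohort? Default
#'   `FALSE`.
#' @param estimator,conf_level,zero_cell_policy Passed to [associate()].
#' @return One-row data frame of association statistics plus `outcome`
#'   and `n_eligible` columns; a rule no drug satisfies yields an
#'   undefined (NA) odds ratio.
#' @export
evaluate_rule <- function(catalog, rule, outcome = c("dili", "severe"),
                          missing_policy = c("negative", "exclude"),
                          include_kis = FALSE,
                          estimator = c("cross_product", "conditional_mle"),
                          conf_level = 0.95,
                          zero_cell_policy = c("haldane", "error")) {
  outcome <- match.arg(outcome)
  missing_policy <- match.arg(missing_policy)
  estimator <- match.arg(estimator)
  zero_cell_policy <- match.arg(zero_cell_policy)
  if (is.null(catalog$severity)) catalog <- grade_catalog(catalog)
  if (!include_kis)
    catalog <- catalog[!is_kinase_inhibitor(catalog), , drop = FALSE]
  arms <- outcome_arms(catalog, outcome)
  cohort <- catalog[arms$keep, , drop = FALSE]
  positive <- arms$positive
  exposed <- rule_exposure(cohort, rule, missing_policy)
  keep <- !is.na(exposed)
  exposed <- exposed[keep]; positive <- positive[keep]
  tab <- dili_2x2(sum(exposed & positive), sum(exposed & !positive),
                  sum(!exposed & positive), sum(!exposed & !positive))
  res <- suppressWarnings(
    associate(tab, label = rule$label, estimator = estimator,
              conf_level = conf_level, zero_cell_policy = zero_cell_policy))
  res$outcome <- outcome
  res$n_eligible <- sum(keep)
  res
}

#' Evaluate every rule of a predicate library
#'
#' @param catalog A `dili_catalog`.
#' @param library Predicate library, default [canonical_predicates()].
#' @param ... Passed to [evaluate_rule()].
#' @return Data frame with one row per enumerated rule.
#' @export
evaluate_all_rules <- function(catalog, library = canonical_predicates(), ...) {
  rules <- enumerate_rules(library)
  do.call(rbind, lapply(rules, function(r) evaluate_rule(catalog, r, ...)))
}

#' Rank rule results
#'
#' @param results Data frame of association results.
#' @param key `"or"` or `"ppv"` (descending) or `"p"` (ascending).
#' @return The data frame reordered; undefined odds ratios last, ties
#'   broken by label.
#' @export
rank_rules <- function(results, key = c("or", "ppv", "p")) {
  key <- match.arg(key)
  vals <- results[[key]]
  undef <- is.na(results$or)
  sort_key <- if (key == "p") ifelse(is.na(vals), Inf, vals)
              else ifelse(is.na(vals), -Inf, -vals)
  out <- results[order(undef, sort_key, results$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference rule contingency counts from a published oral-drug cohort
#'
#' 2x2 cell counts for the canonical threshold rules in a published
#' cohort of 1,223 FDA-approved oral drugs (1,179 after excluding the
#' 44 kinase inhibitors), against any DILI and against severe DILI.
#' Cells follow the [dili_2x2()] layout: `a` rule-positive with the
#' outcome, `b` rule-positive without, `c` rule-negative with, `d`
#' rule-negative without. These counts let the headline statistics of
#' that cohort (for the rule of four: OR 8.28, PPV 88% against DILI) be
#' recomputed exactly without the underlying drug-level data.
#'
#' @return Data frame with columns `label`, `outcome`, `a`, `b`, `c`, `d`.
#' @export
reference_rule_counts <- function() {
  lab <- function(...) paste(..., sep = " and ")
  logp <- "LogP >= 3"; ddd <- "DDD >= 100"; lm <- "LM >= 50%"
  mw <- "400 <= MW < 600"
  dili <- data.frame(
    label = c(logp, ddd, lm,
              lab(logp, ddd), lab(logp, lm), lab(ddd, lm),
              lab(logp, ddd, lm), lab(mw, logp, ddd, lm)),
    outcome = "dili",
    a = c(229, 339, 324, 130, 148, 186, 84, 22),
    b = c(210, 289, 247, 72, 114, 92, 34, 3),
    c = c(335, 225, 240, 434, 416, 378, 480, 542),
    d = c(405, 326, 368, 543, 501, 523, 581, 612),
    stringsAsFactors = FALSE)
  severe <- data.frame(
    label = c(ddd, lm,
              lab(logp, ddd), lab(logp, lm), lab(ddd, lm),
              lab(logp, ddd, lm), lab(mw, logp, ddd, lm)),
    outcome = "severe",
    a = c(166, 155, 65, 71, 93, 42, 10),
    b = c(289, 247, 72, 114, 92, 34, 3),
    c = c(91, 102, 192, 186, 164, 215, 247),
    d = c(326, 368, 543, 501, 523, 581, 612),
    stringsAsFactors = FALSE)
  rbind(dili, severe)
}
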