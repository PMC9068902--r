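# ATC category scans: association of every category at hierarchy
# levels 1-4 with DILI or with severe DILI.

#' Eligible rows and outcome indicator under an outcome mode
#'
#' `"dili"` contrasts any DILI (severe or less-severe) against none.
#' `"severe"` contrasts severe against none, excluding less-severe
#' drugs from both arms.
#'
#' @param catalog A graded `dili_catalog`.
#' @param outcome `"dili"` or `"severe"`.
#' @return List with `keep` (logical rows retained) and `positive`
#'   (logical outcome among retained rows).
#' @keywords internal
outcome_arms <- function(catalog, outcome = c("dili", "severe")) {
  outcome <- match.arg(outcome)
  if (is.null(catalog$severity)) catalog <- grade_catalog(catalog)
  sev <- as.character(catalog$severity)
  if (outcome == "dili") {
    keep <- rep(TRUE, nrow(catalog))
    positive <- sev %in% c("severe", "less_severe")
  } else {
    keep <- sev != "less_severe"
    positive <- sev[keep] == "severe"
  }
  list(keep = keep, positive = positive)
}

#' Scan ATC categories for DILI association
#'
#' For every distinct ATC prefix at the requested hierarchy level,
#' builds the 2x2 table (exposed = drugs carrying any code in the
#' category; outcome per `outcome`) and computes its association
#' statistics. A drug counts once per category even when several of its
#' codes share the prefix; drugs without ATC codes sit in the unexposed
#' arm of every category. Categories covering every eligible drug or
#' none are skipped, as are categories with fewer than `min_exposed`
#' members.
#'
#' @param catalog A `dili_catalog` (graded on the fly if needed).
#' @param level ATC hierarchy level, 1 to 4.
#' @param outcome `"dili"` or `"severe"`; see [outcome_arms()].
#' @param min_exposed Minimum exposed-arm size for a category to be
#'   reported, default 1.
#' @param estimator,conf_level,zero_cell_policy Passed to [associate()].
#' @return Data frame of association results, one row per category,
#'   ordered by label, with a `level` column.
#' @export
scan_atc <- function(catalog, level, outcome = c("dili", "severe"),
                     min_exposed = 1,
                     estimator = c("cross_product", "conditional_mle"),
                     conf_level = 0.95,
                     zero_cell_policy = c("haldane", "error")) {
  outcome <- match.arg(outcome)
  estimator <- match.arg(estimator)
  zero_cell_policy <- match.arg(zero_cell_policy)
  if (is.null(catalog$severity)) catalog <- grade_catalog(catalog)
  arms <- outcome_arms(catalog, outcome)
  codes <- catalog$atc_codes[arms$keep]
  positive <- arms$positive
  n <- length(codes)
  prefixes <- lapply(codes, function(x) {
    x <- x[nchar(x) >= .atc_level_lengths[level]]
    unique(atc_prefix(x, level))
  })
  cats <- sort(unique(unlist(prefixes)))
  rows <- lapply(cats, function(cat) {
    exposed <- vapply(prefixes, function(p) cat %in% p, logical(1))
    ne <- sum(exposed)
    if (ne < min_exposed || ne == 0L || ne == n) return(NULL)
    tab <- dili_2x2(sum(exposed & positive), sum(exposed & !positive),
                    sum(!exposed & positive), sum(!exposed & !positive))
    res <- suppressWarnings(
      associate(tab, label = cat, estimator = estimator,
                conf_level = conf_level, zero_cell_policy = zero_cell_policy))
    res$level <- level
    res
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- associate(dili_2x2(1, 0, 0, 0))[0, ]
    out$level <- integer(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Filter and rank association results
#'
#' Retains results whose (optionally Benjamini-Hochberg adjusted)
#' p-value is at most `alpha`, sorted by descending odds ratio with
#' ties broken by ascending p then label. Undefined odds ratios sort
#' last.
#'
#' @param results Data frame of association results.
#' @param alpha Significance level, default 0.05.
#' @param correction `"none"` (raw Fisher p, the default) or
#'   `"benjamini_hochberg"`.
#' @return The filtered, ranked data frame with an added `p_adj` column.
#' @export
filter_and_rank <- function(results, alpha = 0.05,
                            correction = c("none", "benjamini_hochberg")) {
  correction <- match.arg(correction)
  if (nrow(results) == 0L) {
    results$p_adj <- numeric(0)
    return(results)
  }
  results$p_adj <- if (correction == "benjamini_hochberg")
    stats::p.adjust(results$p, method = "BH") else results$p
  keep <- !is.na(results$p_adj) & results$p_adj <= alpha
  out <- results[keep, , drop = FALSE]
  or_key <- ifelse(is.na(out$or), -Inf, out$or)
  out <- out[order(-or_key, out$p, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
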