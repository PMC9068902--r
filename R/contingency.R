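# Exact 2x2 association statistics: odds ratios (cross-product and
# conditional-MLE), Woolf confidence intervals, two-sided Fisher exact
# p-values and positive predictive values.

#' Build a 2x2 contingency table
#'
#' Cell layout follows the exposure-by-outcome convention:
#' `a` exposed & outcome-positive, `b` exposed & outcome-negative,
#' `c` unexposed & positive, `d` unexposed & negative.
#'
#' @param a,b,c,d Non-negative integer counts, total at least 1.
#' @return A `dili_2x2` object.
#' @export
dili_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("2x2 cells must be non-negative integers")
  if (sum(cells) < 1) stop("2x2 table must contain at least one observation")
  cells <- stats::setNames(as.list(as.integer(round(cells))),
                           c("a", "b", "c", "d"))
  structure(cells, class = "dili_2x2")
}

#' @export
print.dili_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome+", "outcome-")))
  print(m)
  invisible(x)
}

.haldane <- function(tab) {
  tab2 <- tab
  tab2$a <- tab$a + 0.5; tab2$b <- tab$b + 0.5
  tab2$c <- tab$c + 0.5; tab2$d <- tab$d + 0.5
  tab2
}

#' Odds ratio of a 2x2 table
#'
#' The default `cross_product` estimator is (a d)/(b c). The
#' `conditional_mle` estimator maximises the conditional likelihood
#' under the noncentral hypergeometric model (the estimate reported by
#' [stats::fisher.test()]); the two differ noticeably for extreme
#' tables. Zero cells in the denominator are handled by
#' `zero_cell_policy`: `"haldane"` adds 0.5 to all four cells before the
#' cross-product (with a warning), `"error"` refuses.
#'
#' @param tab A `dili_2x2`.
#' @param estimator `"cross_product"` (default) or `"conditional_mle"`.
#' @param zero_cell_policy `"haldane"` (default) or `"error"`; applies
#'   to the cross-product estimator only.
#' @return Positive odds ratio (possibly 0 or `Inf` for the
#'   conditional MLE of degenerate tables).
#' @examples
#' odds_ratio(dili_2x2(22, 3, 542, 612)) # 8.28
#' @export
odds_ratio <- function(tab, estimator = c("cross_product", "conditional_mle"),
                       zero_cell_policy = c("haldane", "error")) {
  estimator <- match.arg(estimator)
  zero_cell_policy <- match.arg(zero_cell_policy)
  if (estimator == "conditional_mle") {
    m <- matrix(c(tab$a, tab$b, tab$c, tab$d), 2, 2, byrow = TRUE)
    return(unname(stats::fisher.test(m)$estimate))
  }
  if (tab$b * tab$c == 0) {
    if (zero_cell_policy == "error")
      stop(sprintf("odds ratio undefined: zero cell in table (%d, %d, %d, %d)",
                   tab$a, tab$b, tab$c, tab$d))
    warning("zero cell: applying Haldane-Anscombe correction (+0.5 to all cells)",
            call. = FALSE)
    tab <- .haldane(tab)
  }
  (tab$a * tab$d) / (tab$b * tab$c)
}

#' Woolf confidence interval for an odds ratio
#'
#' Log-normal interval exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' Requires all four cells positive; a zero cell triggers the
#' Haldane-Anscombe correction (or an error, per policy).
#'
#' @param tab A `dili_2x2`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param zero_cell_policy `"haldane"` (default) or `"error"`.
#' @return Numeric `c(low, high)`.
#' @examples
#' woolf_ci(dili_2x2(22, 3, 542, 612)) # (2.46, 27.82)
#' @export
woolf_ci <- function(tab, level = 0.95,
                     zero_cell_policy = c("haldane", "error")) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("`level` must lie in (0, 1)")
  if (min(tab$a, tab$b, tab$c, tab$d) == 0) {
    if (zero_cell_policy == "error")
      stop("Woolf CI undefined with a zero cell; use the Haldane correction")
    warning("zero cell: applying Haldane-Anscombe correction (+0.5 to all cells)",
            call. = FALSE)
    tab <- .haldane(tab)
  }
  lor <- log((tab$a * tab$d) / (tab$b * tab$c))
  se <- sqrt(1 / tab$a + 1 / tab$b + 1 / tab$c + 1 / tab$d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = exp(lor - z * se), high = exp(lor + z * se))
}

#' Two-sided Fisher exact p-value
#'
#' Sums, over all tables sharing the observed margins, the
#' hypergeometric point probabilities no larger than that of the
#' observed table (with a relative tolerance of 1e-7 for floating-point
#' ties). Degenerate margins (an empty row or column) give p = 1.
#'
#' @param tab A `dili_2x2`.
#' @return p-value in \[0, 1\].
#' @examples
#' fisher_exact_p(dili_2x2(22, 3, 542, 612)) # 4.82e-05
#' @export
fisher_exact_p <- function(tab) {
  m <- tab$a + tab$b          # exposed margin
  n2 <- tab$c + tab$d         # unexposed margin
  k <- tab$a + tab$c          # outcome-positive margin
  if (m == 0 || n2 == 0 || k == 0 || (tab$b + tab$d) == 0) return(1)
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- probs[support == tab$a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Positive predictive value of a 2x2 table
#'
#' @param tab A `dili_2x2`.
#' @return 100 * a / (a + b) in percent, or `NA` when no drug is
#'   rule-positive (a + b = 0).
#' @export
ppv <- function(tab) {
  if (tab$a + tab$b == 0) return(NA_real_)
  100 * tab$a / (tab$a + tab$b)
}

#' Full association statistics for one 2x2 table
#'
#' Bundles the odds ratio, Woolf confidence interval, Fisher exact
#' p-value and PPV into a one-row data frame, the common currency of
#' the category scans and the rule engine. Statistics are kept at full
#' precision; see [format_associations()] for report-style rounding.
#' A table with no exposed drugs yields an undefined (NA) odds ratio
#' and interval.
#'
#' @param tab A `dili_2x2`.
#' @param label Human-readable label of the exposure (category or rule).
#' @param estimator Odds-ratio estimator, see [odds_ratio()].
#' @param conf_level Confidence level for the Woolf interval.
#' @param zero_cell_policy Zero-cell handling, see [odds_ratio()].
#' @return One-row data frame with columns `label`, `a`, `b`, `c`, `d`,
#'   `or`, `ci_low`, `ci_high`, `p`, `ppv`, `estimator`.
#' @export
associate <- function(tab, label = "",
                      estimator = c("cross_product", "conditional_mle"),
                      conf_level = 0.95,
                      zero_cell_policy = c("haldane", "error")) {
  estimator <- match.arg(estimator)
  zero_cell_policy <- match.arg(zero_cell_policy)
  p <- fisher_exact_p(tab)
  if (tab$a + tab$b == 0 || tab$c + tab$d == 0) {
    or <- NA_real_; ci <- c(NA_real_, NA_real_); pv <- ppv(tab)
  } else {
    or <- odds_ratio(tab, estimator, zero_cell_policy)
    ci <- woolf_ci(tab, conf_level, zero_cell_policy)
    pv <- ppv(tab)
  }
  data.frame(label = label, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
             or = or, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             p = p, ppv = pv, estimator = estimator,
             stringsAsFactors = FALSE)
}

#' Report-style formatting of association results
#'
#' Rounds at the reporting layer only: odds ratios, interval bounds and
#' PPV to 2 decimal places, p-values to 3 significant digits in
#' scientific notation.
#'
#' @param results Data frame as produced by [associate()] and friends.
#' @return Data frame of the same shape with character statistic columns.
#' @export
format_associations <- function(results) {
  out <- results
  two <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  out$or <- two(results$or)
  out$ci_low <- two(results$ci_low)
  out$ci_high <- two(results$ci_high)
  out$ppv <- two(results$ppv)
  out$p <- ifelse(is.na(results$p), "",
                  format(signif(results$p, 3), scientific = TRUE))
  out
}
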