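test_that("cross-product odds ratio reproduces reference tables", {
  expect_equal(round(odds_ratio(dili_2x2(22, 3, 542, 612)), 2), 8.28)
  expect_equal(round(odds_ratio(dili_2x2(10, 3, 247, 612)), 2), 8.26)
  expect_equal(odds_ratio(dili_2x2(1, 1, 1, 1)), 1.0)
})

test_that("swapping exposure rows inverts the cross-product odds ratio", {
  set.seed(31)
  for (i in 1:50) {
    cells <- sample.int(40, 4, replace = TRUE)
    tab <- do.call(dili_2x2, as.list(cells))
    swapped <- dili_2x2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(odds_ratio(tab), 1 / odds_ratio(swapped), tolerance = 1e-12)
  }
})

test_that("zero cells follow the requested policy", {
  tab <- dili_2x2(5, 0, 3, 7)
  expect_error(odds_ratio(tab, zero_cell_policy = "error"), "zero cell")
  expect_warning(or <- odds_ratio(tab, zero_cell_policy = "haldane"),
                 "Haldane")
  expect_equal(or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(woolf_ci(tab, zero_cell_policy = "error"), "zero cell")
})

test_that("conditional MLE solves the conditional score equation", {
  # at the conditional MLE psi, the noncentral-hypergeometric mean of
  # the a-cell equals its observed value
  cond_mean <- function(tab, psi) {
    m <- tab$a + tab$b; n2 <- tab$c + tab$d; k <- tab$a + tab$c
    xs <- max(0, k - n2):min(k, m)
    logw <- lchoose(m, xs) + lchoose(n2, k - xs) + xs * log(psi)
    w <- exp(logw - max(logw))
    sum(xs * w) / sum(w)
  }
  for (cells in list(c(10, 5, 3, 12), c(22, 3, 542, 612), c(4, 9, 7, 2))) {
    tab <- do.call(dili_2x2, as.list(cells))
    psi_hat <- odds_ratio(tab, estimator = "conditional_mle")
    expect_equal(cond_mean(tab, psi_hat), tab$a, tolerance = 1e-4)
  }
  # the two estimators differ for extreme tables
  ki_like <- dili_2x2(43, 1, 562, 617)
  expect_lt(odds_ratio(ki_like, estimator = "conditional_mle"),
            odds_ratio(ki_like, estimator = "cross_product"))
})

test_that("Woolf intervals reproduce reference tables and are log-symmetric", {
  ci <- woolf_ci(dili_2x2(22, 3, 542, 612))
  expect_equal(round(unname(ci), 2), c(2.46, 27.82))
  ci2 <- woolf_ci(dili_2x2(10, 3, 247, 612))
  expect_equal(round(unname(ci2), 2), c(2.25, 30.26))
  ci3 <- woolf_ci(dili_2x2(1, 1, 1, 1))
  expect_equal(log(ci3[["low"]]), -log(ci3[["high"]]), tolerance = 1e-12)
})

test_that("Woolf interval contains the cross-product OR for positive tables", {
  set.seed(32)
  for (i in 1:50) {
    tab <- do.call(dili_2x2, as.list(sample.int(60, 4, replace = TRUE)))
    or <- odds_ratio(tab)
    ci <- woolf_ci(tab)
    expect_true(ci[["low"]] <= or && or <= ci[["high"]])
  }
})

test_that("Fisher exact p matches enumeration, transposition and stats::fisher.test", {
  expect_equal(signif(fisher_exact_p(dili_2x2(22, 3, 542, 612)), 3), 4.82e-05)
  expect_equal(fisher_exact_p(dili_2x2(0, 5, 0, 7)), 1.0)
  set.seed(33)
  for (i in 1:60) {
    cells <- sample(0:25, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    tab <- do.call(dili_2x2, as.list(cells))
    p <- fisher_exact_p(tab)
    expect_equal(p, do.call(fisher_enum_oracle, as.list(cells)),
                 tolerance = 1e-10)
    transposed <- dili_2x2(cells[1], cells[3], cells[2], cells[4])
    expect_equal(p, fisher_exact_p(transposed), tolerance = 1e-12)
    m <- matrix(cells, 2, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0))
      expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-6)
  }
})

test_that("PPV is the rule-positive fraction with the outcome, in percent", {
  expect_equal(ppv(dili_2x2(22, 3, 542, 612)), 88.00)
  expect_equal(round(ppv(dili_2x2(10, 3, 247, 612)), 2), 76.92)
  expect_equal(ppv(dili_2x2(0, 5, 1, 1)), 0)
  expect_true(is.na(ppv(dili_2x2(0, 0, 1, 1))))
})

test_that("associate flags tables with no exposed arm as undefined", {
  res <- associate(dili_2x2(0, 0, 5, 7), label = "empty rule")
  expect_true(is.na(res$or) && is.na(res$ci_low) && is.na(res$ppv))
  expect_equal(res$p, 1)
})

test_that("report formatting rounds only at the reporting layer", {
  res <- associate(dili_2x2(22, 3, 542, 612), label = "rule")
  expect_gt(abs(res$or - 8.28), 0)           # full precision retained
  fmt <- format_associations(res)
  expect_identical(fmt$or, "8.28")
  expect_identical(fmt$ppv, "88.00")
  expect_match(fmt$p, "e-05")
})
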