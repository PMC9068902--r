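test_that("threshold predicates honour half-open bounds and missing policies", {
  mw_pred <- threshold_predicate("MW", "interval", c(400, 600))
  expect_true(evaluate_predicate(450, mw_pred))
  expect_true(evaluate_predicate(400, mw_pred))   # closed lower bound
  expect_false(evaluate_predicate(600, mw_pred))  # open upper bound
  lm_pred <- threshold_predicate("LM", "ge", 50)
  expect_false(evaluate_predicate(NA_real_, lm_pred, "negative"))
  expect_true(is.na(evaluate_predicate(NA_real_, lm_pred, "exclude")))
  expect_error(threshold_predicate("MW", "interval", c(600, 400)), "low < high")
})

test_that("rule labels are canonical regardless of predicate order", {
  lib <- canonical_predicates()
  shuffled <- risk_rule(lib[c("LM", "LOGP", "MW", "DDD")])
  expect_identical(shuffled$label,
                   "400 <= MW < 600 and LogP >= 3 and DDD >= 100 and LM >= 50%")
  expect_error(risk_rule(list(lib$MW, lib$MW)), "one predicate per property")
})

test_that("enumerate_rules builds all non-empty conjunctions in canonical order", {
  lib <- canonical_predicates()
  rules4 <- enumerate_rules(lib)
  expect_length(rules4, 15L)
  expect_length(enumerate_rules(lib["LOGP"]), 1L)
  rules3 <- enumerate_rules(lib[c("LOGP", "DDD", "LM")])
  expect_equal(vapply(rules3, `[[`, character(1), "label"),
               c("DDD >= 100", "LM >= 50%", "LogP >= 3",
                 "DDD >= 100 and LM >= 50%", "LogP >= 3 and DDD >= 100",
                 "LogP >= 3 and LM >= 50%",
                 "LogP >= 3 and DDD >= 100 and LM >= 50%"))
  sizes <- vapply(rules4, function(r) length(r$predicates), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("adding a predicate never increases the exposed count", {
  cat0 <- random_catalog(150, seed = 51)
  lib <- canonical_predicates()
  for (i in 1:20) {
    sub <- sample(4, sample(3, 1))
    rule <- risk_rule(lib[sub])
    bigger <- risk_rule(lib[unique(c(sub, sample(setdiff(1:4, sub), 1)))])
    expect_lte(sum(rule_exposure(cat0, bigger)), sum(rule_exposure(cat0, rule)))
  }
})

test_that("all rules share one denominator under the negative missing policy", {
  cat0 <- grade_catalog(random_catalog(200, seed = 52))
  res <- evaluate_all_rules(cat0, outcome = "dili", missing_policy = "negative")
  totals <- res$a + res$b + res$c + res$d
  expect_equal(length(unique(totals)), 1L)
  expect_equal(unique(totals), sum(!is_kinase_inhibitor(cat0)))
  # exclude policy shrinks denominators for rules touching missing values
  res_ex <- evaluate_all_rules(cat0, missing_policy = "exclude")
  expect_true(all(res_ex$a + res_ex$b + res_ex$c + res_ex$d <= totals[1]))
})

test_that("evaluate_rule matches a brute-force per-record filter", {
  cat0 <- grade_catalog(random_catalog(120, seed = 53))
  rule <- risk_rule(canonical_predicates()[c("LOGP", "DDD")])
  res <- evaluate_rule(cat0, rule, outcome = "dili", include_kis = TRUE)
  sev <- as.character(cat0$severity)
  exposed <- vapply(seq_len(nrow(cat0)), function(i) {
    lp <- cat0$logp[i]; dd <- cat0$ddd[i]
    (!is.na(lp) && lp >= 3) && (!is.na(dd) && dd >= 100)
  }, logical(1))
  pos <- sev != "none"
  expect_equal(c(res$a, res$b, res$c, res$d),
               c(sum(exposed & pos), sum(exposed & !pos),
                 sum(!exposed & pos), sum(!exposed & !pos)))
  # KI exclusion removes the L01XE drugs from the cohort
  res_noki <- evaluate_rule(cat0, rule, outcome = "dili", include_kis = FALSE)
  expect_equal(res_noki$a + res_noki$b + res_noki$c + res_noki$d,
               sum(!is_kinase_inhibitor(cat0)))
})

test_that("a catalog forced to the published cells reproduces the headline rule", {
  cat0 <- counts_catalog(22, 3, 542, 612)
  rule <- risk_rule(canonical_predicates())
  res <- evaluate_rule(cat0, rule, outcome = "dili")
  expect_equal(c(res$a, res$b, res$c, res$d), c(22, 3, 542, 612))
  expect_equal(round(res$or, 2), 8.28)
  expect_equal(round(res$ci_low, 2), 2.46)
  expect_equal(round(res$ci_high, 2), 27.82)
  expect_equal(res$ppv, 88.00)
  expect_equal(signif(res$p, 3), 4.82e-05)
})

test_that("a rule no drug satisfies yields a flagged undefined result", {
  cat0 <- grade_catalog(dili_catalog(drug_id = c("a", "b"), mw = c(100, 200),
                                     endpoints = list("hepatitis", character(0))))
  rule <- risk_rule(canonical_predicates()["MW"])
  res <- evaluate_rule(cat0, rule)
  expect_equal(res$a + res$b, 0)
  expect_true(is.na(res$or))
})

test_that("rank_rules orders by the requested key with undefined results last", {
  ref <- reference_rule_counts()
  ref <- ref[ref$outcome == "dili", ]
  res <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i)
    associate(dili_2x2(ref$a[i], ref$b[i], ref$c[i], ref$d[i]), ref$label[i])))
  ranked <- rank_rules(res, key = "or")
  expect_match(ranked$label[1], "^400 <= MW < 600")
  expect_equal(ranked$or, sort(res$or, decreasing = TRUE))
  # reference sort oracle on a random set with an undefined entry
  res2 <- rbind(res, associate(dili_2x2(0, 0, 5, 5), "undef"))
  ranked2 <- rank_rules(res2, key = "p")
  expect_identical(ranked2$label[nrow(ranked2)], "undef")
  defined <- ranked2[ranked2$label != "undef", ]
  expect_equal(defined$p, sort(res$p))
})
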