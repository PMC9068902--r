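test_that("normalization standardizes each protein column with the n-1 divisor", {
  z <- normalize_docking(cbind(p1 = c(-7, -9)), clip_bound = NULL)
  expect_equal(unname(z[, 1]), c(1, -1) / sqrt(2), tolerance = 1e-12)
  set.seed(61)
  m <- matrix(rnorm(200, -7, 2), 20, 10,
              dimnames = list(sprintf("d%02d", 1:20), sprintf("p%02d", 1:10)))
  m[sample(length(m), 15)] <- NA
  z <- normalize_docking(m, clip_bound = NULL)
  expect_equal(unname(colMeans(z, na.rm = TRUE)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd, na.rm = TRUE)), rep(1, 10),
               tolerance = 1e-9)
  expect_identical(is.na(z), is.na(m))   # missing entries stay missing
})

test_that("degenerate columns raise errors naming the protein", {
  m <- cbind(good = c(-7, -8, -9), flat = c(-5, -5, -5))
  expect_error(normalize_docking(m), "'flat'.*zero score variance")
  m2 <- cbind(good = c(-7, -8, -9), sparse = c(-5, NA, NA))
  expect_error(normalize_docking(m2), "'sparse'.*fewer than 2")
})

test_that("normalization is idempotent and clipping winsorizes", {
  set.seed(62)
  m <- matrix(rnorm(300, -7, 1.5), 30, 10)
  z <- normalize_docking(m, clip_bound = NULL)
  z2 <- normalize_docking(z, clip_bound = NULL)
  expect_equal(z2, z, tolerance = 1e-9, ignore_attr = TRUE)
  zc <- normalize_docking(m, clip_bound = 1)
  expect_true(all(abs(zc) <= 1))
  expect_equal(attr(zc, "clip_bound"), 1)
})

test_that("shifting one protein column leaves the others' z-scores unchanged", {
  set.seed(63)
  m <- matrix(rnorm(100, -7, 1), 20, 5)
  m2 <- m; m2[, 3] <- m2[, 3] + 5
  z <- normalize_docking(m, clip_bound = NULL)
  z2 <- normalize_docking(m2, clip_bound = NULL)
  expect_equal(z2[, -3], z[, -3], tolerance = 1e-12)
  expect_equal(z2[, 3], z[, 3], tolerance = 1e-9)  # constant shift cancels
})

test_that("per-drug mean scores match a per-row loop and drop empty rows", {
  expect_equal(unname(drug_mean_score(rbind(a = c(1, -1)))), 0)
  set.seed(64)
  m <- matrix(rnorm(20), 5, 4, dimnames = list(letters[1:5], NULL))
  m[2, c(1, 3)] <- NA
  s <- drug_mean_score(m)
  for (i in 1:5)
    expect_equal(s[[rownames(m)[i]]], mean(m[i, ], na.rm = TRUE))
  m[4, ] <- NA
  expect_warning(s2 <- drug_mean_score(m), "no docking scores")
  expect_false("d" %in% names(s2))
})

test_that("docking matrices round-trip through wide TSV and read from long", {
  set.seed(65)
  m <- matrix(rnorm(12, -7), 4, 3,
              dimnames = list(c("d1", "d2", "d3", "d4"), c("pA", "pB", "pC")))
  m[2, 2] <- NA
  path <- tempfile(fileext = ".tsv")
  write_docking_matrix(m, path)
  expect_equal(read_docking_matrix(path), m, tolerance = 1e-12)
  long <- tempfile(fileext = ".tsv")
  df <- expand.grid(drug_id = rownames(m), protein_id = colnames(m),
                    stringsAsFactors = FALSE)
  df$score <- m[cbind(df$drug_id, df$protein_id)]
  write.table(df[!is.na(df$score), ], long, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_docking_matrix(long, format = "long")[rownames(m), colnames(m)],
               m, tolerance = 1e-12)
})

test_that("identical scores across groups give H = 0 and p = 1", {
  scores <- setNames(rep(-1.5, 8), sprintf("d%d", 1:8))
  classes <- setNames(rep(c("none", "less_severe"), each = 4), names(scores))
  cmp <- compare_severity_groups(scores, classes)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("the rank test is invariant under strictly monotone transforms", {
  set.seed(66)
  scores <- setNames(rnorm(60), sprintf("d%02d", 1:60))
  classes <- setNames(sample(c("none", "less_severe", "severe"), 60, TRUE),
                      names(scores))
  a <- compare_severity_groups(scores, classes)
  b <- compare_severity_groups(exp(scores / 2) - 5, classes)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("undersized groups are dropped with a warning", {
  scores <- setNames(c(rnorm(5), 0), sprintf("d%d", 1:6))
  classes <- setNames(c(rep("none", 3), rep("less_severe", 2), "severe"),
                      names(scores))
  expect_warning(cmp <- compare_severity_groups(scores, classes), "severe")
  expect_false("severe" %in% names(cmp$medians))
  solo <- setNames(c("none", "severe"), c("d1", "d2"))
  expect_error(suppressWarnings(
    compare_severity_groups(scores[1:2], solo)), "at least two")
})

test_that("one-vs-rest ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(67)
  cat0 <- dili_catalog(drug_id = sprintf("d%02d", 1:30),
                       atc_codes = c(rep(list("L01XE01"), 8),
                                     rep(list("C07AB02"), 22)))
  scores <- setNames(c(rnorm(8, -1), rnorm(22, 0)), cat0$drug_id)
  res <- atc_one_vs_rest(scores, cat0, level = 4)
  member <- 1:8
  tt <- t.test(scores[member], scores[-member], var.equal = TRUE)
  row <- res[res$category == "L01XE", ]
  expect_equal(row$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  expect_equal(row$group_mean, mean(scores[member]))
  expect_true(all(diff(res$p) >= 0))   # sorted by significance
})

test_that("top_proteins ranks ascending means with sd then id tie-breaks", {
  m <- cbind(pC = rep(0, 4), pA = rep(-1, 4), pB = rep(-2, 4)) +
    matrix(0, 4, 3)
  rownames(m) <- sprintf("d%d", 1:4)
  # add tiny per-column jitter with equal means to exercise tie-breaks
  res <- top_proteins(m + 0, k = 2)
  expect_equal(res$protein_id, c("pB", "pA"))
  tie <- cbind(a2 = c(-1, -1), a1 = c(-2, 0), a0 = c(-1.5, -0.5))
  rownames(tie) <- c("d1", "d2")
  res_tie <- top_proteins(tie, k = 3)  # all means -1: sd asc, then id
  expect_equal(res_tie$protein_id, c("a2", "a0", "a1"))
  expect_equal(nrow(top_proteins(tie, k = 10)), 3L)
  # brute-force oracle on a random matrix
  set.seed(68)
  rm <- matrix(rnorm(60, -7), 6, 10,
               dimnames = list(sprintf("d%d", 1:6), sprintf("q%02d", 1:10)))
  res_r <- top_proteins(rm, drugs = c("d1", "d3", "d5"), k = 10)
  sub <- rm[c("d1", "d3", "d5"), ]
  expect_equal(res_r$protein_id, colnames(sub)[order(colMeans(sub))])
  expect_equal(res_r$mean, unname(sort(colMeans(sub))))
  expect_error(top_proteins(rm, drugs = "nope"), "not in matrix")
})
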