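# Shared fixtures and independent oracles, all built in code.

# Small hand-built catalog exercising multi-valued cells, missing
# values and every severity class.
toy_catalog <- function() {
  dili_catalog(
    drug_id = c("d1", "d2", "d3", "d4", "d5"),
    name = c("alpha", "beta", "gamma", "delta", "epsilon"),
    mw = c(450, 120.5, NA, 580, 350),
    logp = c(4.2, NA, 1.1, 3.5, 2.0),
    ddd = c(200, 50, 10, 150, NA),
    lm_percent = c(80, 20, NA, 95, 40),
    atc_codes = list(c("L01XE01", "C07AB02"), "A10BA02", character(0),
                     "L01XE07", "N02BE01"),
    endpoints = list(c("fatality", "jaundice"), "hepatitis", character(0),
                     c("liver_failure", "hepatitis"), "abnormal_biomarkers"),
    black_box = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    withdrawn = FALSE,
    hys_law = c(FALSE, FALSE, FALSE, FALSE, FALSE))
}

# Random catalog with arbitrary endpoint/code structure for oracles.
random_catalog <- function(n, seed) {
  set.seed(seed)
  vocab <- endpoint_vocabulary()
  prefixes <- c("A10BA", "C07AB", "L01XE", "L01XA", "N02BE", "J01CA")
  eps <- lapply(seq_len(n), function(i)
    sample(vocab, sample(0:3, 1), replace = FALSE))
  codes <- lapply(seq_len(n), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) character(0)
    else paste0(sample(prefixes, k), sprintf("%02d", sample.int(9, k)))
  })
  dili_catalog(
    drug_id = sprintf("r%03d", seq_len(n)),
    mw = ifelse(runif(n) < 0.1, NA, exp(rnorm(n, log(350), 0.4))),
    logp = ifelse(runif(n) < 0.1, NA, rnorm(n, 2.5, 1.8)),
    ddd = ifelse(runif(n) < 0.1, NA, sample(c(5, 50, 100, 200, 400), n, TRUE)),
    lm_percent = ifelse(runif(n) < 0.1, NA, runif(n, 0, 100)),
    atc_codes = codes, endpoints = eps,
    black_box = runif(n) < 0.05,
    withdrawn = runif(n) < 0.02,
    hys_law = runif(n) < 0.05)
}

# Catalog engineered so the rule of four yields exactly the requested
# 2x2 cells (a, b, c, d) under the "dili" outcome: rule-positive drugs
# get properties inside every threshold, rule-negative outside; DILI
# drugs get a less-severe endpoint.
counts_catalog <- function(a, b, c, d) {
  n <- a + b + c + d
  pos <- c(rep(TRUE, a + b), rep(FALSE, c + d))
  dili <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  dili_catalog(
    drug_id = sprintf("x%04d", seq_len(n)),
    mw = ifelse(pos, 450, 200),
    logp = ifelse(pos, 4, 0),
    ddd = ifelse(pos, 200, 10),
    lm_percent = ifelse(pos, 80, 10),
    endpoints = lapply(dili, function(y) if (y) "hepatitis" else character(0)))
}

# Independent full-enumeration oracle for the two-sided Fisher exact
# p-value, written against log-binomial coefficients (not dhyper).
fisher_enum_oracle <- function(a, b, c, d, tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1))
  min(1, sum(p[p <= p[xs == a] * (1 + tol)]))
}

write_tmp_catalog <- function(catalog, dialect = "csv") {
  path <- tempfile(fileext = paste0(".", dialect))
  write_catalog(catalog, path, dialect = dialect)
  path
}
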