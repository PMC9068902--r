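# Docking-score matrix handling: column-wise z-score normalization,
# per-drug mean scores, severity-group rank tests, ATC one-vs-rest
# ANOVA scans and protein ranking.

#' Read a docking-score matrix
#'
#' Wide format: TSV with a header, first column `drug_id`, remaining
#' columns one per protein, scores in kcal/mol, empty cells missing.
#' Long format: columns `drug_id`, `protein_id`, `score`.
#'
#' @param path Path to the TSV file.
#' @param format `"wide"` (default) or `"long"`.
#' @return Numeric matrix, rows = drugs, columns = proteins.
#' @export
read_docking_matrix <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "")
  if (format == "wide") {
    if (names(raw)[1] != "drug_id")
      .stop_schema("wide docking matrix must start with a drug_id column")
    m <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(m)) .stop_schema("non-numeric docking scores")
    rownames(m) <- raw$drug_id
  } else {
    need <- c("drug_id", "protein_id", "score")
    if (!all(need %in% names(raw)))
      .stop_schema("long docking matrix needs drug_id, protein_id, score")
    drugs <- unique(raw$drug_id); prots <- unique(raw$protein_id)
    m <- matrix(NA_real_, length(drugs), length(prots),
                dimnames = list(drugs, prots))
    m[cbind(match(raw$drug_id, drugs), match(raw$protein_id, prots))] <-
      as.numeric(raw$score)
  }
  if (anyDuplicated(rownames(m)))
    .stop_schema("duplicate drug_id in docking matrix")
  m
}

#' Write a docking-score matrix (wide TSV)
#'
#' @param m Numeric matrix with drug row names and protein column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_docking_matrix <- function(m, path) {
  out <- data.frame(drug_id = rownames(m),
                    as.data.frame(m, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Column-standardize a docking-score matrix
#'
#' Per protein column j: Z_ij = (X_ij - mean_j) / sd_j, with the sample
#' standard deviation (divisor N_j - 1) over the non-missing entries of
#' that column. Missing entries stay missing and do not enter the
#' column statistics. If `clip_bound` is set (default 4), standardized
#' values are winsorized into \[-clip_bound, +clip_bound\]; pass `NULL`
#' for unclipped z-scores, which renormalize to themselves.
#'
#' @param m Numeric matrix, rows = drugs, columns = proteins.
#' @param clip_bound Non-negative clipping bound or `NULL`, default 4.
#' @return Matrix of the same shape with attribute `clip_bound`.
#' @examples
#' normalize_docking(cbind(p1 = c(-7, -9)), clip_bound = NULL) # +/- 0.7071
#' @export
normalize_docking <- function(m, clip_bound = 4) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  if (!is.null(clip_bound) && (length(clip_bound) != 1L || clip_bound < 0))
    stop("`clip_bound` must be a single non-negative number or NULL")
  n_obs <- colSums(!is.na(m))
  prot <- if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m)
  if (any(n_obs < 2L))
    stop(sprintf("protein column '%s' has fewer than 2 docking scores",
                 prot[which(n_obs < 2L)[1]]))
  mu <- colMeans(m, na.rm = TRUE)
  sd_j <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sd_j == 0 | is.na(sd_j)))
    stop(sprintf("protein column '%s' has zero score variance; cannot standardize",
                 prot[which(sd_j == 0 | is.na(sd_j))[1]]))
  z <- sweep(sweep(m, 2, mu, "-"), 2, sd_j, "/")
  if (!is.null(clip_bound)) z <- pmin(pmax(z, -clip_bound), clip_bound)
  attr(z, "clip_bound") <- if (is.null(clip_bound)) NA_real_ else clip_bound
  z
}

#' Per-drug mean docking score
#'
#' @param z Numeric matrix (normalized or raw), rows = drugs.
#' @return Named numeric vector of row means over non-missing entries;
#'   drugs with no scores are dropped with a warning.
#' @export
drug_mean_score <- function(z) {
  n_obs <- rowSums(!is.na(z))
  if (any(n_obs == 0L)) {
    warning(sprintf("dropping %d drug(s) with no docking scores",
                    sum(n_obs == 0L)), call. = FALSE)
    z <- z[n_obs > 0L, , drop = FALSE]
  }
  rowMeans(z, na.rm = TRUE)
}

#' Compare docking scores across DILI severity groups
#'
#' Kruskal-Wallis rank test (with tie correction, via
#' [stats::kruskal.test()]) across the severity groups, plus one-sided
#' Wilcoxon rank-sum comparisons of each DILI group (less-severe,
#' severe, and both pooled) against the no-DILI group, testing whether
#' DILI drugs score lower (bind more strongly). Groups with fewer than
#' two scored drugs are dropped with a warning.
#'
#' @param scores Named numeric vector of per-drug scores
#'   (names = drug_id).
#' @param classes Named character/factor of severity classes for the
#'   same drugs (`"none"`, `"less_severe"`, `"severe"`).
#' @param grouping `"three_groups"` (default) keeps the three severity
#'   groups; `"dili_vs_none"` pools severe and less-severe.
#' @return A `severity_comparison` list: `statistic` (H), `df`,
#'   `p_value`, `medians`, and `pairwise` (one-sided p-values vs none).
#' @export
compare_severity_groups <- function(scores, classes,
                                    grouping = c("three_groups", "dili_vs_none")) {
  grouping <- match.arg(grouping)
  ids <- intersect(names(scores), names(classes))
  if (length(ids) == 0L) stop("scores and classes share no drug ids")
  x <- scores[ids]
  g <- as.character(classes[ids])
  if (grouping == "dili_vs_none")
    g[g %in% c("severe", "less_severe")] <- "dili"
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("dropping group(s) with fewer than 2 drugs: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !g %in% small
    x <- x[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2L)
    stop("need at least two non-degenerate groups to compare")
  if (length(unique(x)) == 1L) {
    # all scores tied: no evidence of any group difference
    kw <- list(statistic = c(H = 0),
               parameter = c(df = length(unique(g)) - 1L), p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, factor(g))
  }
  none <- x[g == "none"]
  dili_groups <- setdiff(unique(g), "none")
  pairwise <- NULL
  if (length(none) >= 2L && length(dili_groups)) {
    cmp <- lapply(dili_groups, function(grp) {
      w <- stats::wilcox.test(x[g == grp], none, alternative = "less",
                              exact = FALSE)
      data.frame(group = grp, n = sum(g == grp),
                 median = stats::median(x[g == grp]),
                 p_less_than_none = w$p.value, stringsAsFactors = FALSE)
    })
    if (grouping == "three_groups" &&
        all(c("severe", "less_severe") %in% dili_groups)) {
      pooled <- x[g %in% c("severe", "less_severe")]
      w <- stats::wilcox.test(pooled, none, alternative = "less", exact = FALSE)
      cmp[[length(cmp) + 1L]] <-
        data.frame(group = "all_dili", n = length(pooled),
                   median = stats::median(pooled),
                   p_less_than_none = w$p.value, stringsAsFactors = FALSE)
    }
    pairwise <- do.call(rbind, cmp)
  }
  structure(list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value,
                 medians = tapply(x, g, stats::median),
                 pairwise = pairwise),
            class = "severity_comparison")
}

#' @export
print.severity_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat("group medians:\n"); print(round(unclass(x$medians), 4))
  if (!is.null(x$pairwise)) {
    cat("one-sided comparisons vs the no-DILI group (lower scores):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' One-vs-rest ANOVA over ATC categories
#'
#' For each ATC category at the requested level, compares the per-drug
#' mean docking scores of its members against all other scored drugs
#' with a two-group one-way ANOVA (equal-variance F test). Categories
#' with fewer than `min_members` members, or fewer than 2 non-members,
#' are skipped.
#'
#' @param scores Named numeric vector of per-drug scores.
#' @param catalog A `dili_catalog` supplying ATC codes.
#' @param level ATC hierarchy level, 2 to 4.
#' @param min_members Minimum category size, default 2.
#' @return Data frame `category`, `level`, `n_group`, `f`, `p`,
#'   `group_mean`, `rest_mean`, sorted by ascending p.
#' @export
atc_one_vs_rest <- function(scores, catalog, level, min_members = 2) {
  if (!level %in% 2:4) stop("`level` must be 2, 3 or 4")
  ids <- intersect(names(scores), catalog$drug_id)
  x <- scores[ids]
  codes <- catalog$atc_codes[match(ids, catalog$drug_id)]
  prefixes <- lapply(codes, function(cc) {
    cc <- cc[nchar(cc) >= .atc_level_lengths[level]]
    unique(atc_prefix(cc, level))
  })
  cats <- sort(unique(unlist(prefixes)))
  rows <- lapply(cats, function(cat) {
    member <- vapply(prefixes, function(p) cat %in% p, logical(1))
    if (sum(member) < min_members || sum(!member) < 2L) return(NULL)
    grp <- factor(member, levels = c(FALSE, TRUE))
    ow <- stats::oneway.test(x ~ grp, var.equal = TRUE)
    data.frame(category = cat, level = level, n_group = sum(member),
               f = unname(ow$statistic), p = ow$p.value,
               group_mean = mean(x[member]), rest_mean = mean(x[!member]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(category = character(0), level = integer(0),
                      n_group = integer(0), f = numeric(0), p = numeric(0),
                      group_mean = numeric(0), rest_mean = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank proteins by mean docking score over a drug subset
#'
#' Proteins are sorted by ascending mean score (most negative = best
#' predicted binding) over the selected drugs; ties break by ascending
#' standard deviation, then protein id. By default the raw
#' (kcal/mol-scale) matrix is ranked; pass an already normalized matrix
#' to rank on the standardized scale.
#'
#' @param m Numeric matrix, rows = drugs, columns = proteins.
#' @param drugs Optional character vector of drug ids restricting the
#'   subset; default all rows.
#' @param k Number of proteins to return, default 5; larger than the
#'   protein count returns the full ranking.
#' @return Data frame `protein_id`, `mean`, `sd`, `n`, best first.
#' @export
top_proteins <- function(m, drugs = NULL, k = 5) {
  if (!is.null(drugs)) {
    missing_ids <- setdiff(drugs, rownames(m))
    if (length(missing_ids))
      stop(sprintf("drug(s) not in matrix: %s",
                   paste(missing_ids, collapse = ", ")))
    m <- m[drugs, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty drug subset")
  means <- colMeans(m, na.rm = TRUE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  prot <- if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m)
  ord <- order(means, sds, prot)
  out <- data.frame(protein_id = prot[ord], mean = means[ord], sd = sds[ord],
                    n = colSums(!is.na(m))[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, k)
}
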