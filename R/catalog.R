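# Drug catalog data model: one row per drug, with set-valued ATC codes and
# label endpoints held as list-columns, plus regulatory flags.

#' Endpoint vocabulary
#'
#' The seven liver-injury endpoints recognised on drug labels. The first
#' three define the severe group; the last four the less-severe group.
#'
#' @return Character vector of the seven endpoint tokens.
#' @export
endpoint_vocabulary <- function() {
  c("fatality", "liver_failure", "liver_transplantation",
    "hepatitis", "hepatomegaly", "jaundice", "abnormal_biomarkers")
}

severe_endpoints <- function() endpoint_vocabulary()[1:3]
less_severe_endpoints <- function() endpoint_vocabulary()[4:7]

# ATC prefix length for hierarchy levels 1..5 (codes are 1/3/4/5/7 chars)
.atc_level_lengths <- c(1L, 3L, 4L, 5L, 7L)

# schema of the on-disk catalog table
.catalog_columns <- c("drug_id", "name", "mw", "logp", "ddd", "lm_percent",
                      "atc_codes", "endpoints", "black_box", "withdrawn",
                      "hys_law")

.stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("dili_schema_error", "error", "condition")))
}

#' Validate an ATC code string
#'
#' ATC codes are hierarchical: a letter (anatomical group), two digits,
#' a letter, a letter, two digits, truncatable at levels 1-5, giving
#' lengths 1, 3, 4, 5 or 7.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the code is well-formed.
#' @export
is_valid_atc <- function(code) {
  patterns <- c(
    "^[A-Z]$",
    "^[A-Z][0-9]{2}$",
    "^[A-Z][0-9]{2}[A-Z]$",
    "^[A-Z][0-9]{2}[A-Z]{2}$",
    "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
  )
  out <- rep(FALSE, length(code))
  for (p in patterns) out <- out | grepl(p, code)
  out
}

#' Leading prefix of an ATC code at a hierarchy level
#'
#' Levels 1 to 4 of the ATC hierarchy correspond to the leading 1, 3, 4
#' and 5 characters of a code.
#'
#' @param code Character vector of ATC codes.
#' @param level Integer hierarchy level, 1 to 4.
#' @return Character vector of prefixes.
#' @examples
#' atc_prefix("L01XE01", 4) # "L01XE"
#' atc_prefix("A10BA02", 2) # "A10"
#' @export
atc_prefix <- function(code, level) {
  if (length(level) != 1L || !level %in% 1:4)
    stop("`level` must be a single integer in 1..4")
  len <- .atc_level_lengths[level]
  short <- nchar(code) < len
  if (any(short))
    stop(sprintf("ATC code '%s' is shorter than the level-%d prefix length %d",
                 code[short][1], level, len))
  substr(code, 1L, len)
}

#' Average defined daily dose
#'
#' When several defined daily doses are reported for a drug (for example
#' for different body weights), the catalog stores their unweighted
#' arithmetic mean.
#'
#' @param values Numeric vector of positive doses in mg/day.
#' @return The mean dose, or `NA_real_` for an empty vector.
#' @export
average_ddd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  if (any(values <= 0)) stop("defined daily doses must be positive")
  mean(values)
}

#' Construct a drug catalog from vectors
#'
#' @param drug_id Character vector of unique drug identifiers.
#' @param name Drug names.
#' @param mw Molecular weight in Da (positive; `NA` = missing).
#' @param logp Octanol-water partition coefficient (`NA` = missing).
#' @param ddd Defined daily dose in mg/day (positive; `NA` = missing).
#' @param lm_percent Extent of liver metabolism in percent, 0-100.
#' @param atc_codes List of character vectors of ATC codes per drug.
#' @param endpoints List of character vectors of endpoint tokens per drug.
#' @param black_box,withdrawn,hys_law Logical regulatory flags.
#' @return A `dili_catalog` data frame.
#' @export
dili_catalog <- function(drug_id, name = drug_id,
                         mw = NA_real_, logp = NA_real_, ddd = NA_real_,
                         lm_percent = NA_real_,
                         atc_codes = vector("list", length(drug_id)),
                         endpoints = vector("list", length(drug_id)),
                         black_box = FALSE, withdrawn = FALSE,
                         hys_law = FALSE) {
  n <- length(drug_id)
  atc_codes <- lapply(atc_codes, function(x) toupper(as.character(x)))
  endpoints <- lapply(endpoints, as.character)
  cat <- data.frame(drug_id = as.character(drug_id),
                    name = rep_len(as.character(name), n),
                    mw = rep_len(as.numeric(mw), n),
                    logp = rep_len(as.numeric(logp), n),
                    ddd = rep_len(as.numeric(ddd), n),
                    lm_percent = rep_len(as.numeric(lm_percent), n),
                    stringsAsFactors = FALSE)
  cat$atc_codes <- atc_codes
  cat$endpoints <- endpoints
  cat$black_box <- rep_len(as.logical(black_box), n)
  cat$withdrawn <- rep_len(as.logical(withdrawn), n)
  cat$hys_law <- rep_len(as.logical(hys_law), n)
  class(cat) <- c("dili_catalog", "data.frame")
  validate_catalog(cat)
  cat
}

#' Validate a drug catalog
#'
#' Checks identifier uniqueness, property ranges (mw > 0, ddd > 0,
#' lm_percent in \[0, 100\]), ATC code shape and endpoint vocabulary.
#'
#' @param catalog A `dili_catalog`.
#' @param rows Optional original row numbers used in error messages.
#' @return The catalog, invisibly; signals a `dili_schema_error` otherwise.
#' @export
validate_catalog <- function(catalog, rows = seq_len(nrow(catalog))) {
  dup <- catalog$drug_id[duplicated(catalog$drug_id)]
  if (length(dup))
    .stop_schema(sprintf("duplicate drug_id: %s", paste(unique(dup), collapse = ", ")))
  bad <- function(ok, what) {
    idx <- which(!ok)
    if (length(idx))
      .stop_schema(sprintf("%s in row %s", what, paste(rows[idx], collapse = ", ")))
  }
  bad(is.na(catalog$mw) | catalog$mw > 0, "mw must be positive")
  bad(is.na(catalog$ddd) | catalog$ddd > 0, "ddd must be positive")
  bad(is.na(catalog$lm_percent) |
        (catalog$lm_percent >= 0 & catalog$lm_percent <= 100),
      "lm_percent must lie in [0, 100]")
  code_rows <- rep(rows, lengths(catalog$atc_codes))
  codes <- unlist(catalog$atc_codes, use.names = FALSE)
  if (length(codes)) {
    ok <- is_valid_atc(codes)
    if (any(!ok))
      .stop_schema(sprintf("malformed ATC code '%s' in row %s",
                           codes[!ok][1], code_rows[!ok][1]))
  }
  ep_rows <- rep(rows, lengths(catalog$endpoints))
  eps <- unlist(catalog$endpoints, use.names = FALSE)
  if (length(eps)) {
    ok <- eps %in% endpoint_vocabulary()
    if (any(!ok))
      .stop_schema(sprintf("unknown endpoint token '%s' in row %s",
                           eps[!ok][1], ep_rows[!ok][1]))
  }
  invisible(catalog)
}

#' Read a drug catalog from CSV/TSV
#'
#' The table must carry a header with columns `drug_id`, `name`, `mw`,
#' `logp`, `ddd`, `lm_percent`, `atc_codes`, `endpoints`, `black_box`,
#' `withdrawn`, `hys_law`. Multi-valued cells (`atc_codes`, `endpoints`)
#' are pipe-separated; empty cells are missing values; flags are 0/1.
#' ATC codes are upper-cased on read.
#'
#' @param path Path to the file (or a connection).
#' @param dialect `"csv"` or `"tsv"`.
#' @param multi_sep Separator inside multi-valued cells, default `"|"`.
#' @return A validated `dili_catalog`.
#' @export
read_catalog <- function(path, dialect = c("csv", "tsv"), multi_sep = "|") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL,
                           comment.char = "")
  missing_cols <- setdiff(.catalog_columns, names(raw))
  if (length(missing_cols))
    .stop_schema(sprintf("catalog is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  num <- function(col) {
    x <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad))
      .stop_schema(sprintf("non-numeric %s in row %s", col,
                           paste(bad, collapse = ", ")))
    out[x == ""] <- NA_real_
    out
  }
  flag <- function(col) {
    x <- trimws(raw[[col]])
    if (!all(x %in% c("0", "1")))
      .stop_schema(sprintf("flag column %s must be 0/1 (row %s)", col,
                           paste(which(!x %in% c("0", "1")), collapse = ", ")))
    x == "1"
  }
  split_multi <- function(col) {
    lapply(trimws(raw[[col]]), function(x) {
      if (!nzchar(x)) character(0)
      else trimws(strsplit(x, multi_sep, fixed = TRUE)[[1]])
    })
  }
  dili_catalog(drug_id = trimws(raw$drug_id),
               name = raw$name,
               mw = num("mw"), logp = num("logp"), ddd = num("ddd"),
               lm_percent = num("lm_percent"),
               atc_codes = split_multi("atc_codes"),
               endpoints = split_multi("endpoints"),
               black_box = flag("black_box"),
               withdrawn = flag("withdrawn"),
               hys_law = flag("hys_law"))
}

#' Write a drug catalog to CSV/TSV
#'
#' Inverse of [read_catalog()]: multi-valued columns are pipe-joined,
#' missing values become empty cells, flags 0/1.
#'
#' @param catalog A `dili_catalog`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param multi_sep Separator inside multi-valued cells.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, dialect = c("csv", "tsv"),
                          multi_sep = "|") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                                     scientific = FALSE))
  out <- data.frame(
    drug_id = catalog$drug_id,
    name = catalog$name,
    mw = fmt_num(catalog$mw),
    logp = fmt_num(catalog$logp),
    ddd = fmt_num(catalog$ddd),
    lm_percent = fmt_num(catalog$lm_percent),
    atc_codes = vapply(catalog$atc_codes, paste, character(1), collapse = multi_sep),
    endpoints = vapply(catalog$endpoints, paste, character(1), collapse = multi_sep),
    black_box = as.integer(catalog$black_box),
    withdrawn = as.integer(catalog$withdrawn),
    hys_law = as.integer(catalog$hys_law),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Kinase-inhibitor membership
#'
#' Small-molecule kinase inhibitors are the ATC level-4 class `L01XE`.
#' A drug is a member if any of its ATC codes starts with that prefix.
#'
#' @param catalog A `dili_catalog`.
#' @param prefix Level-4 ATC prefix defining the class, default `"L01XE"`.
#' @return Logical vector along the catalog rows.
#' @export
is_kinase_inhibitor <- function(catalog, prefix = "L01XE") {
  vapply(catalog$atc_codes,
         function(codes) any(nchar(codes) >= nchar(prefix) &
                               startsWith(codes, prefix)),
         logical(1))
}

#' @export
print.dili_catalog <- function(x, ...) {
  cat(sprintf("<dili_catalog> %d drugs\n", nrow(x)))
  show <- utils::head(as.data.frame(x)[, c("drug_id", "name", "mw", "logp",
                                           "ddd", "lm_percent")], 6L)
  print(show, ...)
  invisible(x)
}
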