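#' Construct and validate a long-format cohort table
#'
#' A cohort table holds one row per person-phase with one column per
#' registry variable. Values are category labels; `NA` marks a missing
#' answer. Validation enforces uniqueness of `(id, phase)` pairs, domain
#' membership of non-missing values and within-person constancy of static
#' variables. Out-of-domain values are coerced to missing with a warning
#' and a tally attached as attribute `n_out_of_domain` (outliers are
#' treated as missing values rather than dropped rows).
#'
#' @param df a data.frame with columns `id`, `phase` and one column per
#'   registry variable.
#' @param registry a [variable_registry()].
#' @return a validated data.frame of class `cohort_table` with character
#'   variable columns, integer `phase`, and attribute `n_out_of_domain`.
#' @export
as_cohort <- function(df, registry) {
  if (!all(c("id", "phase") %in% names(df)))
    stop("cohort table must have 'id' and 'phase' columns")
  vars <- reg_names(registry)
  extra <- setdiff(names(df), c("id", "phase", vars))
  if (length(extra))
    stop("unknown variable column(s): ", paste(extra, collapse = ", "))
  missing_cols <- setdiff(vars, names(df))
  if (length(missing_cols))
    stop("missing variable column(s): ", paste(missing_cols, collapse = ", "))

  out <- data.frame(id = as.character(df$id), phase = as.integer(df$phase),
                    stringsAsFactors = FALSE)
  n_bad <- 0L
  for (v in vars) {
    x <- as.character(df[[v]])
    x[!is.na(x) & x == ""] <- NA_character_
    bad <- !is.na(x) & !(x %in% reg_domain(registry, v))
    if (any(bad)) {
      n_bad <- n_bad + sum(bad)
      x[bad] <- NA_character_
    }
    out[[v]] <- x
  }
  if (n_bad > 0L)
    warning(n_bad, " out-of-domain value(s) treated as missing")

  key <- paste(out$id, out$phase, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (id, phase) pair(s) in cohort table")

  for (v in vars) {
    if (reg_role(registry, v) != "static") next
    obs <- !is.na(out[[v]])
    n_lvl <- tapply(out[[v]][obs], out$id[obs],
                    function(z) length(unique(z)))
    if (length(n_lvl) && any(n_lvl > 1L))
      stop("static variable '", v, "' varies within a person")
  }

  attr(out, "n_out_of_domain") <- n_bad
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read a cohort from a delimited text file
#'
#' Expects a long-format file with header `id,phase,<var1>,...`; one row per
#' person-phase. Tokens equal to `missing` (and empty cells) are read as
#' missing; any other token outside a variable's declared domain is coerced
#' to missing with a warning tally, mirroring the treatment of outliers as
#' missing values.
#'
#' @param path file path.
#' @param registry a [variable_registry()].
#' @param missing token(s) marking a missing value (default empty string and
#'   `"NA"`).
#' @param sep field delimiter.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, registry, missing = c("", "NA"), sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = missing,
                          check.names = FALSE, quote = "\"",
                          stringsAsFactors = FALSE)
  as_cohort(df, registry)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: in-domain values round-trip losslessly.
#'
#' @param table a `cohort_table`.
#' @param path file path.
#' @param missing token written for missing values (default empty string).
#' @param sep field delimiter.
#' @export
write_cohort <- function(table, path, missing = "", sep = ",") {
  utils::write.table(table, path, sep = sep, na = missing,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-phase frequency table of one variable
#'
#' Counts respondents (non-missing values) per category at one phase and
#' reports the percentage among respondents, the convention used in
#' descriptive cohort tables.
#'
#' @param table a `cohort_table`.
#' @param variable variable name.
#' @param phase phase index (integer).
#' @param registry the registry the table was validated against.
#' @return a data.frame with columns `category`, `count`, `percent`
#'   (unrounded, percentages summing to 100) and attribute `respondents`.
#' @examples
#' \dontrun{
#' summarize_cohort(tab, "memory", 5, reg)
#' }
#' @export
summarize_cohort <- function(table, variable, phase, registry) {
  dom <- reg_domain(registry, variable)  # errors on unknown variable
  x <- table[[variable]][table$phase == phase]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L)
    stop("no respondents for '", variable, "' at phase ", phase,
         ": percentages undefined")
  counts <- as.integer(table(factor(x, levels = dom)))
  out <- data.frame(category = dom, count = counts,
                    percent = 100 * counts / n, stringsAsFactors = FALSE)
  attr(out, "respondents") <- n
  out
}

## ---- internal: integer coding ---------------------------------------------

## 0-based integer code matrix (rows = person-phases, cols = variables);
## NA preserved. All counting and scoring works on this representation.
cohort_codes <- function(table, registry) {
  vars <- reg_names(registry)
  m <- matrix(NA_integer_, nrow = nrow(table), ncol = length(vars),
              dimnames = list(NULL, vars))
  for (v in vars)
    m[, v] <- match(table[[v]], reg_domain(registry, v)) - 1L
  m
}

## indices of (previous, current) rows for consecutive phase pairs of the
## same person; used for transition counting
consecutive_pairs <- function(table) {
  ord <- order(table$id, table$phase)
  id <- table$id[ord]
  ph <- table$phase[ord]
  i <- seq_len(length(ord) - 1L)
  if (nrow(table) < 2L) return(cbind(prev = integer(0), cur = integer(0)))
  ok <- id[i] == id[i + 1L] & ph[i + 1L] == ph[i] + 1L
  cbind(prev = ord[i][ok], cur = ord[i + 1L][ok])
}
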