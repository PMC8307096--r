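#' Cohort data model and CSV schema
#'
#' A cohort is a per-participant table with one row per scanned volunteer:
#' group membership (clinical high-risk "CHR" or healthy control "HC"),
#' the glutathione concentration estimate and its Cramer-Rao lower bound
#' (CRLB, in percent, used as a spectral-quality inclusion filter), and the
#' clinical scores analysed downstream (SOFAS functioning, SOPS symptom
#' total, CAST cannabis score, AUDIT-C alcohol score), plus age and gender.
#'
#' @name cohort-io
NULL

cohort_columns <- c("id", "group", "gsh", "gsh_crlb", "sofas", "sops_total",
                    "cast", "audit_c", "age", "gender")

#' Construct a validated cohort table
#'
#' @param records data frame with the schema columns (`id`, `group`, `gsh`,
#'   `gsh_crlb`, `sofas`, `sops_total`, `cast`, `audit_c`, `age`, `gender`);
#'   extra columns are preserved untouched. Missing values are allowed in
#'   `gsh`, `gsh_crlb`, `sops_total`, `cast` and `audit_c`.
#' @param provenance free-text origin of the table (source file or
#'   generator seed).
#' @return A tibble of class `cohort_table` with a `provenance` attribute.
#' @export
cohort_table <- function(records, provenance = "constructed in memory") {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  records$id <- as.character(records$id)
  records$group <- toupper(trimws(as.character(records$group)))
  records$gender <- tolower(trimws(as.character(records$gender)))
  validate_cohort(records)
  records <- records[c(cohort_columns, setdiff(names(records), cohort_columns))]
  structure(records,
            provenance = provenance,
            class = c("cohort_table", class(records)))
}

# Row/column-naming validation of the participant schema.
validate_cohort <- function(records) {
  fail <- function(row, col, msg)
    stop(sprintf("invalid cohort record (row %d, column '%s'): %s", row, col, msg))
  if (anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)][1L]
    fail(which(records$id == dup)[2L], "id", sprintf("duplicate id '%s'", dup))
  }
  check_range <- function(col, lo, hi, integer = FALSE) {
    v <- records[[col]]
    for (i in seq_along(v)) {
      if (is.na(v[i])) next
      if (!is.numeric(v[i]) || v[i] < lo || v[i] > hi)
        fail(i, col, sprintf("value %s outside [%s, %s]", format(v[i]), lo, hi))
      if (integer && v[i] != round(v[i]))
        fail(i, col, sprintf("value %s is not an integer score", format(v[i])))
    }
  }
  bad_group <- which(!is.na(records$group) & !records$group %in% c("CHR", "HC"))
  if (length(bad_group) > 0L)
    fail(bad_group[1L], "group",
         sprintf("label '%s' is not one of CHR, HC", records$group[bad_group[1L]]))
  bad_gender <- which(!is.na(records$gender) & !records$gender %in% c("male", "female"))
  if (length(bad_gender) > 0L)
    fail(bad_gender[1L], "gender",
         sprintf("label '%s' is not one of male, female", records$gender[bad_gender[1L]]))
  bad_gsh <- which(!is.na(records$gsh) & records$gsh <= 0)
  if (length(bad_gsh) > 0L)
    fail(bad_gsh[1L], "gsh", "concentration must be positive (mM)")
  bad_crlb <- which(!is.na(records$gsh_crlb) & records$gsh_crlb < 0)
  if (length(bad_crlb) > 0L)
    fail(bad_crlb[1L], "gsh_crlb", "CRLB percent must be nonnegative")
  check_range("sofas", 0, 100, integer = TRUE)
  check_range("sops_total", 0, Inf, integer = TRUE)
  check_range("cast", 6, 30, integer = TRUE)
  check_range("audit_c", 0, 12, integer = TRUE)
  invisible(records)
}

#' @export
print.cohort_table <- function(x, ...) {
  counts <- table(factor(x$group, levels = c("CHR", "HC")))
  cat(sprintf("<cohort_table> %d participants (CHR %d, HC %d)\n",
              nrow(x), counts[["CHR"]], counts[["HC"]]))
  cat("  provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

#' Read a cohort CSV
#'
#' Expects the header `id,group,gsh,gsh_crlb,sofas,sops_total,cast,audit_c,
#' age,gender` (extra columns are kept as opaque extras). Empty cells become
#' `NA`; group labels are case-insensitive and canonicalized to upper case.
#'
#' @param path path to a UTF-8, comma-delimited CSV with a header row.
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("cohort file ", path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  num <- function(col) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0L)
      stop(sprintf("invalid cohort record (row %d, column '%s'): '%s' is not numeric",
                   bad[1L], col, v[bad[1L]]))
    out
  }
  chr <- function(col) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    v
  }
  records <- tibble::tibble(
    id = chr("id"), group = chr("group"),
    gsh = num("gsh"), gsh_crlb = num("gsh_crlb"),
    sofas = num("sofas"), sops_total = num("sops_total"),
    cast = num("cast"), audit_c = num("audit_c"),
    age = num("age"), gender = chr("gender")
  )
  extras <- setdiff(names(raw), cohort_columns)
  for (e in extras) records[[e]] <- raw[[e]]
  cohort_table(records, provenance = paste0("file:", path))
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, and the
#' output is byte-stable given identical input, so reports can be diffed.
#'
#' @param table a [cohort_table()].
#' @param path destination file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  df <- as.data.frame(table)
  # 17 significant digits so doubles survive the round trip bit-for-bit
  for (col in names(df)) {
    if (is.numeric(df[[col]]))
      df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                          formatC(df[[col]], digits = 17, format = "g"))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Quality-control filter on the glutathione CRLB
#'
#' Retains participants whose glutathione CRLB is strictly below `threshold`
#' percent (the study's inclusion rule uses 30%). Records with a missing CRLB
#' are excluded; original order is preserved. Idempotent, and monotone in the
#' threshold.
#'
#' @param table a [cohort_table()].
#' @param threshold positive CRLB percentage; strict `<` comparison.
#' @return The filtered [cohort_table()].
#' @export
filter_by_crlb <- function(table, threshold = 30) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be a positive percentage")
  keep <- !is.na(table$gsh_crlb) & table$gsh_crlb < threshold
  out <- table[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- class(table)
  out
}
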