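# Cohort container: a validated tibble of patient records.

SEX_LEVELS <- c("male", "female")
DIAGNOSIS_LEVELS <- c("stroke", "msk", "cancer", "other")
SCORE_MAX <- 300L

COHORT_COLUMNS <- c(
  "patient_id", "age_years", "sex", "diagnosis",
  "clinfit_admission", "clinfit_discharge", "td_level"
)

#' Construct a validated patient cohort
#'
#' A cohort is a tibble of patient records with one row per inpatient:
#' ClinFIT total scores at admission and (optionally) discharge on the
#' 0-300 raw scale, the RCS v2 Therapy Disciplines level (0-3) as the
#' ordinal rehabilitation-intensity reference, and demographics. Unknown
#' extra columns are kept as pass-through.
#'
#' @param records data frame with columns `patient_id`, `age_years`,
#'   `sex` (`male`/`female`), `diagnosis` (`stroke`/`msk`/`cancer`/`other`),
#'   `clinfit_admission` (integer 0-300), `clinfit_discharge` (integer
#'   0-300 or `NA`), `td_level` (integer 0-3). Sex and diagnosis are
#'   matched case-insensitively; unknown values are errors, never mapped
#'   silently to `other`.
#' @param provenance free-text label recording where the records came from
#'   (e.g. `"synthetic seed=7"`).
#' @return A `clinstage_cohort`, a tibble with a `provenance` attribute.
#' @export
#' @examples
#' cohort(data.frame(
#'   patient_id = c("a", "b"), age_years = c(70, 55),
#'   sex = c("male", "Female"), diagnosis = c("stroke", "msk"),
#'   clinfit_admission = c(210L, 120L), clinfit_discharge = c(140L, NA),
#'   td_level = c(3L, 1L)
#' ))
cohort <- function(records, provenance = "unspecified") {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "),
          class = "clinstage_schema_error")
  }
  records <- validate_records(records)
  records <- records[c(COHORT_COLUMNS, setdiff(names(records), COHORT_COLUMNS))]
  structure(records,
            class = c("clinstage_cohort", class(tibble::tibble())),
            provenance = provenance)
}

#' @export
print.clinstage_cohort <- function(x, ...) {
  cat(sprintf("<clinstage_cohort> %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

# Coerce/validate raw columns; errors name the offending rows.
validate_records <- function(df) {
  bad_rows <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stopf("%s in row(s): %s", what,
            paste(which(cond), collapse = ", "),
            class = "clinstage_validation_error")
    }
  }
  df$patient_id <- as.character(df$patient_id)
  bad_rows(is.na(df$patient_id) | df$patient_id == "", "missing patient_id")
  if (anyDuplicated(df$patient_id)) {
    stopf("duplicated patient_id in row(s): %s",
          paste(which(duplicated(df$patient_id)), collapse = ", "),
          class = "clinstage_validation_error")
  }

  df$sex <- match_vocab(df$sex, SEX_LEVELS, "sex", required = TRUE)
  df$diagnosis <- match_vocab(df$diagnosis, DIAGNOSIS_LEVELS, "diagnosis",
                              required = TRUE)

  df$age_years <- as.numeric(df$age_years)
  bad_rows(is.na(df$age_years) | df$age_years < 0, "missing or negative age_years")

  df$clinfit_admission <- as_score(df$clinfit_admission)
  bad_rows(attr(df$clinfit_admission, "out_of_range"),
           sprintf("clinfit_admission outside 0-%d", SCORE_MAX))
  attr(df$clinfit_admission, "out_of_range") <- NULL
  bad_rows(is.na(df$clinfit_admission), "missing clinfit_admission")

  df$clinfit_discharge <- as_score(df$clinfit_discharge)
  bad_rows(attr(df$clinfit_discharge, "out_of_range"),
           sprintf("clinfit_discharge outside 0-%d", SCORE_MAX))
  attr(df$clinfit_discharge, "out_of_range") <- NULL

  td <- suppressWarnings(as.integer(df$td_level))
  bad_rows(is.na(td) | td < 0L | td > 3L, "td_level outside 0-3")
  df$td_level <- td
  df
}

# integer score in [0, 300]; flags out-of-range without erroring (caller
# reports row indices)
as_score <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  non_integer <- !is.na(v) & v != floor(v)
  out <- !is.na(v) & (v < 0 | v > SCORE_MAX | non_integer)
  v <- as.integer(ifelse(out, NA, v))
  # restore flagged values' positions for error messages
  structure(v, out_of_range = out)
}

match_vocab <- function(x, levels, field, required = FALSE) {
  lowered <- tolower(trimws(as.character(x)))
  lowered[lowered == ""] <- NA_character_
  unknown <- !is.na(lowered) & !(lowered %in% levels)
  if (any(unknown)) {
    stopf("unknown %s value(s) %s in row(s): %s", field,
          paste(unique(sQuote(lowered[unknown])), collapse = ", "),
          paste(which(unknown), collapse = ", "),
          class = "clinstage_validation_error")
  }
  if (required && anyNA(lowered)) {
    stopf("missing %s in row(s): %s", field,
          paste(which(is.na(lowered)), collapse = ", "),
          class = "clinstage_validation_error")
  }
  factor(lowered, levels = levels)
}

#' Read a patient cohort from CSV
#'
#' Expects comma-separated UTF-8 with a header row. Canonical column names
#' are `patient_id`, `age_years`, `sex`, `diagnosis`, `clinfit_admission`,
#' `clinfit_discharge`, `td_level`; a schema mapping adapts foreign
#' headers. Missing discharge scores are empty cells. Rows that violate
#' the record invariants (scores outside 0-300, TD level outside 0-3,
#' unknown sex/diagnosis) are rejected with row-indexed messages.
#'
#' @param path CSV file path.
#' @param schema optional column mapping: a named character vector
#'   (canonical name -> header in the file) or the path of a JSON/YAML
#'   file holding such a mapping.
#' @return a [cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path, class = "clinstage_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    map <- load_schema(schema)
    missing_src <- setdiff(unname(map), names(df))
    if (length(missing_src) > 0) {
      stopf("schema maps to column(s) absent from file: %s",
            paste(missing_src, collapse = ", "), class = "clinstage_schema_error")
    }
    names(df)[match(unname(map), names(df))] <- names(map)
  }
  cohort(df, provenance = path)
}

load_schema <- function(schema) {
  if (is.character(schema) && is.null(names(schema)) && length(schema) == 1 &&
      file.exists(schema)) {
    schema <- if (grepl("\\.ya?ml$", schema, ignore.case = TRUE)) {
      unlist(yaml::read_yaml(schema))
    } else {
      unlist(jsonlite::read_json(schema, simplifyVector = TRUE))
    }
  }
  if (is.null(names(schema)) || any(names(schema) == "")) {
    stopf("schema must be a named mapping canonical -> file column",
          class = "clinstage_schema_error")
  }
  bad <- setdiff(names(schema), COHORT_COLUMNS)
  if (length(bad) > 0) {
    stopf("schema names unknown canonical column(s): %s",
          paste(bad, collapse = ", "), class = "clinstage_schema_error")
  }
  schema
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field for field. Absent discharge scores become empty cells.
#'
#' @param x a [cohort()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "clinstage_cohort"))
  out <- as.data.frame(x)
  out$sex <- as.character(out$sex)
  out$diagnosis <- as.character(out$diagnosis)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
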