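#' Claims cohort: the audit's tabular unit of analysis
#'
#' A claims cohort is a validated data frame with one row per index claim.
#' Each row carries identifiers (claim, patient, hospital, hospital sector,
#' benefits-package code), 15 logical document-presence flags named by
#' document code (see [document_types()]), and the clinical abstract used by
#' the audit rules: biopsy diagnosis, documented-metastasis status, surgery
#' type and date, chemotherapy claim date, the administered drug list
#' (semicolon-delimited), the regimen strings from the consent form and the
#' clinical notes, a prior-first-line-documentation flag, and a per-claim
#' expert override marking treatment as clinically inappropriate.
#'
#' `claims_cohort()` validates a data frame against this schema and returns
#' it classed as `claims_cohort`. Missingness conventions: `surgery_date`,
#' `regimen_on_consent` and `regimen_in_notes` may be `NA`;
#' `metastasis_documented` is never `NA` -- absence of evidence is the
#' explicit value `"no_documentation"`, because the audit branches on lack
#' of documentation, not on documented absence.
#'
#' @param x a data frame conforming to the cohort schema (see
#'   [cohort_columns()]).
#' @return `x`, column-ordered to the schema, with class `claims_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [claim_record()]
#' @export
claims_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), cols)
  if (length(extra)) {
    stop("unknown cohort column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, cols, drop = FALSE]
  rownames(x) <- NULL
  validate_cohort(x)
  class(x) <- c("claims_cohort", "data.frame")
  x
}

#' @rdname claims_cohort
#' @export
cohort_columns <- function() {
  c(
    "claim_id", "patient_id", "hospital_id", "sector", "package_code",
    document_types(),
    "biopsy_diagnosis", "metastasis_documented", "surgery_type",
    "surgery_date", "chemo_claim_date", "drugs",
    "regimen_on_consent", "regimen_in_notes",
    "prior_first_line_documented", "treatment_override_inappropriate"
  )
}

biopsy_diagnosis_levels <- function() {
  c("breast_cancer", "variant_breast_condition", "other_cancer", "unknown")
}

validate_cohort <- function(x) {
  if (nrow(x) == 0L) {
    return(invisible(x))
  }
  chk_chr <- function(col) {
    v <- x[[col]]
    if (!is.character(v) || anyNA(v) || any(!nzchar(v))) {
      stop("column '", col, "' must be non-missing character", call. = FALSE)
    }
  }
  for (col in c("claim_id", "patient_id", "hospital_id", "package_code")) {
    chk_chr(col)
  }
  dup <- x$claim_id[duplicated(x$claim_id)]
  if (length(dup)) {
    stop("duplicate claim_id in cohort: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  chk_enum <- function(col, levels, allow_na = FALSE) {
    v <- x[[col]]
    bad <- if (allow_na) !is.na(v) & !v %in% levels else is.na(v) | !v %in% levels
    if (any(bad)) {
      stop("invalid value(s) in column '", col, "' for claim(s) ",
           paste(x$claim_id[bad], collapse = ", "),
           " (allowed: ", paste(levels, collapse = ", "), ")", call. = FALSE)
    }
  }
  chk_enum("sector", c("public", "private"))
  chk_enum("biopsy_diagnosis", biopsy_diagnosis_levels())
  chk_enum("metastasis_documented", c("yes", "no_documentation"))
  chk_enum("surgery_type", c("MRM", "BCS", "none_recorded"))
  for (col in c(document_types(), "prior_first_line_documented",
                "treatment_override_inappropriate")) {
    v <- x[[col]]
    if (!is.logical(v) || anyNA(v)) {
      stop("column '", col, "' must be logical with no missing values",
           call. = FALSE)
    }
  }
  for (col in c("surgery_date", "chemo_claim_date")) {
    if (!inherits(x[[col]], "Date")) {
      stop("column '", col, "' must be of class Date", call. = FALSE)
    }
  }
  if (anyNA(x$chemo_claim_date)) {
    bad <- x$claim_id[is.na(x$chemo_claim_date)]
    stop("chemo_claim_date missing for claim(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- x$surgery_type == "none_recorded" & !is.na(x$surgery_date)
  if (any(bad)) {
    stop("surgery_date present but surgery_type is none_recorded for claim(s) ",
         paste(x$claim_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(x$surgery_date) & x$surgery_date > x$chemo_claim_date
  if (any(bad)) {
    stop("surgery_date after chemo_claim_date for claim(s) ",
         paste(x$claim_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.character(x$drugs) || anyNA(x$drugs)) {
    stop("column 'drugs' must be non-missing character (semicolon-delimited)",
         call. = FALSE)
  }
  for (col in c("regimen_on_consent", "regimen_in_notes")) {
    if (!is.character(x[[col]])) {
      stop("column '", col, "' must be character", call. = FALSE)
    }
  }
  invisible(x)
}

#' Construct a single claim record
#'
#' Convenience constructor returning a one-row [claims_cohort()]. Mostly
#' useful for tests, examples, and interactive exploration of the audit
#' rules; bulk data enters through [read_cohort()].
#'
#' @param claim_id,patient_id,hospital_id,sector,package_code identifiers.
#' @param documents character vector of present document codes (subset of
#'   [document_types()]).
#' @param biopsy_diagnosis one of `"breast_cancer"`,
#'   `"variant_breast_condition"`, `"other_cancer"`, `"unknown"`.
#' @param metastasis_documented `"yes"` or `"no_documentation"`.
#' @param surgery_type `"MRM"`, `"BCS"`, or `"none_recorded"`.
#' @param surgery_date,chemo_claim_date `Date` (surgery may be `NA`).
#' @param drugs character vector of administered drug names.
#' @param regimen_on_consent,regimen_in_notes regimen strings, or `NA`.
#' @param prior_first_line_documented logical.
#' @param treatment_override_inappropriate logical expert-review flag.
#' @return a one-row `claims_cohort`.
#' @examples
#' claim_record(drugs = c("paclitaxel"), metastasis_documented = "yes")
#' @export
claim_record <- function(claim_id = "CLM-001",
                         patient_id = "PT-001",
                         hospital_id = "HOSP-01",
                         sector = "public",
                         package_code = "PC-UNLISTED",
                         documents = c("invoice",
                                       "checklist_unlisted_palliative",
                                       "chemotherapy_details",
                                       "consent_form", "biopsy_report"),
                         biopsy_diagnosis = "breast_cancer",
                         metastasis_documented = "no_documentation",
                         surgery_type = "none_recorded",
                         surgery_date = as.Date(NA),
                         chemo_claim_date = as.Date("2019-07-15"),
                         drugs = character(),
                         regimen_on_consent = NA_character_,
                         regimen_in_notes = NA_character_,
                         prior_first_line_documented = FALSE,
                         treatment_override_inappropriate = FALSE) {
  unknown <- setdiff(documents, document_types())
  if (length(unknown)) {
    stop("unknown document-type code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  row <- data.frame(
    claim_id = claim_id, patient_id = patient_id, hospital_id = hospital_id,
    sector = sector, package_code = package_code,
    stringsAsFactors = FALSE
  )
  for (doc in document_types()) {
    row[[doc]] <- doc %in% documents
  }
  row$biopsy_diagnosis <- biopsy_diagnosis
  row$metastasis_documented <- metastasis_documented
  row$surgery_type <- surgery_type
  row$surgery_date <- as.Date(surgery_date)
  row$chemo_claim_date <- as.Date(chemo_claim_date)
  row$drugs <- paste(drugs, collapse = ";")
  row$regimen_on_consent <- regimen_on_consent
  row$regimen_in_notes <- regimen_in_notes
  row$prior_first_line_documented <- prior_first_line_documented
  row$treatment_override_inappropriate <- treatment_override_inappropriate
  claims_cohort(row)
}

#' Is a tissue diagnosis document available?
#'
#' True when the claim file contains either a biopsy report or a fine needle
#' aspiration cytology (FNAC) report -- the two documents accepted as
#' establishing the tissue diagnosis.
#'
#' @param cohort a [claims_cohort()].
#' @return logical vector, one element per claim.
#' @export
biopsy_available <- function(cohort) {
  cohort$biopsy_report | cohort$fnac_report
}

# Split the semicolon-delimited drugs column into per-claim character vectors.
claim_drug_list <- function(cohort) {
  lapply(strsplit(cohort$drugs, ";", fixed = TRUE),
         function(d) trimws(d[nzchar(trimws(d))]))
}

#' Read and write claims cohorts
#'
#' The exchange format is one flat row per claim (auditable in any
#' spreadsheet tool): identifier and clinical columns plus 15 boolean
#' document columns named by document code, drugs as a semicolon-delimited
#' list in one column, dates in ISO 8601 (YYYY-MM-DD). CSV files are
#' comma-separated UTF-8 with a mandatory header and `true`/`false` boolean
#' literals; JSON files are an array of claim objects with the same keys.
#' `write_cohort()` then `read_cohort()` reproduces the cohort exactly.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; default guessed from the file
#'   extension.
#' @param cohort a [claims_cohort()].
#' @return `read_cohort()` returns a [claims_cohort()]; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  raw <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(obj) == 0L) empty_raw_cohort() else
      as.data.frame(lapply(obj, as.character), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0L) {
    if (ncol(raw) == 0L) raw <- empty_raw_cohort()
    return(coerce_raw_cohort(raw))
  }
  coerce_raw_cohort(raw)
}

empty_raw_cohort <- function() {
  cols <- cohort_columns()
  raw <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                       check.names = FALSE, stringsAsFactors = FALSE)
  raw
}

coerce_raw_cohort <- function(raw) {
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), cols)
  if (length(extra)) {
    stop("unknown column(s) in cohort file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[, cols, drop = FALSE]
  ids <- raw$claim_id
  parse_bool <- function(col) {
    v <- tolower(trimws(raw[[col]]))
    out <- ifelse(v %in% c("true", "1"), TRUE,
                  ifelse(v %in% c("false", "0"), FALSE, NA))
    bad <- is.na(out)
    if (any(bad)) {
      stop("claim ", ids[which(bad)[1]], ": column '", col,
           "' has non-boolean value '", raw[[col]][which(bad)[1]], "'",
           call. = FALSE)
    }
    out
  }
  parse_date <- function(col, required) {
    v <- trimws(raw[[col]])
    v[v %in% c("", "NA", "null")] <- NA
    out <- as.Date(rep(NA_integer_, length(v)), origin = "1970-01-01")
    has <- !is.na(v)
    if (any(has)) {
      ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", v[has])
      parsed <- as.Date(ifelse(ok, v[has], NA), format = "%Y-%m-%d")
      # as.Date() with %Y-%m-%d silently rolls nothing but returns NA for
      # impossible dates such as 2019-13-01 or 2019-02-30
      bad <- which(has)[!ok | is.na(parsed)]
      if (length(bad)) {
        stop("claim ", ids[bad[1]], ": column '", col,
             "' has malformed date '", v[bad[1]], "'", call. = FALSE)
      }
      out[has] <- parsed
    }
    if (required && anyNA(out)) {
      stop("claim ", ids[which(is.na(out))[1]], ": column '", col,
           "' must not be missing", call. = FALSE)
    }
    out
  }
  parse_opt_chr <- function(col) {
    v <- raw[[col]]
    blank <- !is.na(v) & (!nzchar(trimws(v)) | v %in% c("NA", "null"))
    v[blank] <- NA_character_
    v
  }
  out <- raw[, c("claim_id", "patient_id", "hospital_id", "sector",
                 "package_code"), drop = FALSE]
  for (doc in document_types()) out[[doc]] <- parse_bool(doc)
  out$biopsy_diagnosis <- raw$biopsy_diagnosis
  out$metastasis_documented <- raw$metastasis_documented
  out$surgery_type <- raw$surgery_type
  out$surgery_date <- parse_date("surgery_date", required = FALSE)
  out$chemo_claim_date <- parse_date("chemo_claim_date", required = TRUE)
  out$drugs <- raw$drugs
  out$regimen_on_consent <- parse_opt_chr("regimen_on_consent")
  out$regimen_in_notes <- parse_opt_chr("regimen_in_notes")
  out$prior_first_line_documented <- parse_bool("prior_first_line_documented")
  out$treatment_override_inappropriate <-
    parse_bool("treatment_override_inappropriate")
  claims_cohort(out)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  cohort <- claims_cohort(cohort)
  format <- resolve_format(match.arg(format), path)
  flat <- as.data.frame(cohort)
  for (doc in c(document_types(), "prior_first_line_documented",
                "treatment_override_inappropriate")) {
    flat[[doc]] <- ifelse(flat[[doc]], "true", "false")
  }
  for (col in c("surgery_date", "chemo_claim_date")) {
    flat[[col]] <- ifelse(is.na(flat[[col]]), "",
                          format(flat[[col]], "%Y-%m-%d"))
  }
  for (col in c("regimen_on_consent", "regimen_in_notes")) {
    flat[[col]] <- ifelse(is.na(flat[[col]]), "", flat[[col]])
  }
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(flat, path, dataframe = "rows", na = "null")
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") {
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json" else "csv"
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat("<claims_cohort> ", nrow(x), " claim(s)",
      if (nrow(x)) paste0(" (public ", sum(x$sector == "public"),
                          ", private ", sum(x$sector == "private"), ")"),
      "\n", sep = "")
  if (nrow(x)) {
    utils::str(x[, c("claim_id", "sector", "biopsy_diagnosis",
                     "metastasis_documented", "chemo_claim_date", "drugs")],
               give.attr = FALSE)
  }
  invisible(x)
}
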