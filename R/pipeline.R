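# End-to-end orchestration behind the command-line front-end
# (inst/scripts/palliaudit.R). Both entry points are ordinary functions so
# the pipeline is fully testable without a shell.

#' Run the audit pipeline on a claims file
#'
#' Reads a claims cohort (and optionally a claims-history file and a drug
#' catalog), audits every claim, and writes the per-claim verdict table, the
#' evidence log, the document-availability table, the determination/reason
#' summary tables, history metrics when a history is given, and a run log
#' recording the inputs, the catalog provenance and MD5 hash, and the
#' package version. Output is deterministic: the same input directory
#' yields byte-identical CSVs.
#'
#' @param claims path to a claims cohort file (CSV or JSON, see
#'   [read_cohort()]).
#' @param out_dir output directory (created if needed).
#' @param catalog path to a YAML drug catalog; default: the shipped catalog.
#' @param history optional path to a claims-history CSV with columns
#'   `patient_id`, `claim_id`, `hospital_id`, `claim_date`.
#' @param verbose print progress to the console.
#' @return invisibly, the exit status `0L`. Validation failures raise
#'   errors (the CLI wrapper maps them to a nonzero exit).
#' @export
cmd_audit <- function(claims, out_dir, catalog = NULL, history = NULL,
                      verbose = FALSE) {
  catalog_path <- if (is.null(catalog)) {
    system.file("extdata", "default_catalog.yaml", package = "palliaudit")
  } else {
    catalog
  }
  if (!file.exists(catalog_path)) {
    stop("catalog file not found: ", catalog_path, call. = FALSE)
  }
  cat_obj <- load_catalog(catalog_path)
  cohort <- read_cohort(claims)
  if (verbose) message("audited input: ", nrow(cohort), " claim(s)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- audit_cohort(cohort, cat_obj)
  per_claim <- as.data.frame(results)
  utils::write.csv(per_claim, file.path(out_dir, "audit.csv"),
                   row.names = FALSE)
  jsonlite::write_json(attr(results, "evidence"),
                       file.path(out_dir, "evidence.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)

  docs <- tabulate_documents(cohort)
  utils::write.csv(as.data.frame(docs), file.path(out_dir, "documents.csv"),
                   row.names = FALSE)

  if (nrow(cohort)) {
    summ <- summarize_audit(results, cohort)
    utils::write.csv(summ$determinations,
                     file.path(out_dir, "determinations.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$reasons, file.path(out_dir, "reasons.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$treatment, file.path(out_dir, "treatment.csv"),
                     row.names = FALSE)
  } else {
    for (f in c("determinations.csv", "reasons.csv", "treatment.csv")) {
      utils::write.csv(data.frame(), file.path(out_dir, f), row.names = FALSE)
    }
  }

  if (!is.null(history)) {
    hist <- read_history(history)
    hm <- history_metrics(
      hist,
      index_claims = setNames(cohort$hospital_id, cohort$patient_id),
      sector_map = setNames(cohort$sector, cohort$patient_id)
    )
    utils::write.csv(hm$by_sector, file.path(out_dir, "history_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(hm$distinct_hospitals,
                     file.path(out_dir, "history_distinct_hospitals.csv"),
                     row.names = FALSE)
  }

  log <- list(
    tool = "palliaudit",
    version = as.character(utils::packageVersion("palliaudit")),
    inputs = list(claims = claims, history = history,
                  catalog = catalog_path),
    catalog_md5 = unname(tools::md5sum(catalog_path)),
    catalog_source = cat_obj$source,
    n_claims = nrow(cohort)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (verbose) message("outputs written to ", out_dir)
  invisible(0L)
}

#' Generate a synthetic cohort to disk
#'
#' Runs [generate_cohort()] and writes the cohort, the claims history, the
#' assigned reason patterns, and a run log recording the seed.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [generator_config()].
#' @param format `"csv"` or `"json"` for the cohort file.
#' @return invisibly, the exit status `0L`.
#' @export
cmd_generate <- function(out_dir, config = generator_config(),
                         format = c("csv", "json")) {
  format <- match.arg(format)
  gen <- generate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(gen$cohort, file.path(out_dir, paste0("cohort.", format)),
               format = format)
  write_history(gen$history, file.path(out_dir, "history.csv"))
  assigned <- attr(gen$cohort, "assigned_pattern")
  utils::write.csv(
    data.frame(claim_id = names(assigned), assigned_pattern = unname(assigned),
               stringsAsFactors = FALSE),
    file.path(out_dir, "assigned_patterns.csv"), row.names = FALSE
  )
  log <- list(
    tool = "palliaudit",
    version = as.character(utils::packageVersion("palliaudit")),
    seed = config$seed,
    n_patients_per_sector = config$n_patients_per_sector,
    reason_mix = as.list(config$reason_mix)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(0L)
}

#' Read and write claims-history files
#'
#' A claims history is one row per claim a patient filed under the scheme
#' (without supporting documentation): `patient_id`, `claim_id`,
#' `hospital_id`, `claim_date` (ISO 8601).
#'
#' @param path CSV file path.
#' @param history a history data frame.
#' @return `read_history()` returns the history data frame; `write_history()`
#'   returns `path` invisibly.
#' @export
read_history <- function(path) {
  if (!file.exists(path)) {
    stop("history file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("patient_id", "claim_id", "hospital_id", "claim_date")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("history file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- as.Date(raw$claim_date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & nzchar(raw$claim_date))
  if (length(bad) || anyNA(parsed)) {
    i <- if (length(bad)) bad[1] else which(is.na(parsed))[1]
    stop("history claim ", raw$claim_id[i], ": malformed claim_date '",
         raw$claim_date[i], "'", call. = FALSE)
  }
  raw$claim_date <- parsed
  raw[, need, drop = FALSE]
}

#' @rdname read_history
#' @export
write_history <- function(history, path) {
  out <- history
  out$claim_date <- format(out$claim_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
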