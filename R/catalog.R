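#' Drug-role catalog
#'
#' The audit never reasons about drug names directly: every decision depends
#' on the *guideline role* of the administered regimen. The catalog maps
#' normalized drug or combination-regimen names to sets of roles:
#'
#' * `first_line_palliative` -- acceptable first-line palliative
#'   chemotherapy for metastatic breast cancer;
#' * `second_line_palliative` -- acceptable after first-line failure;
#' * `non_chemotherapy` -- hormonal or targeted agents that are not
#'   chemotherapy and hence not reimbursable under a chemotherapy package;
#' * `adjuvant_regimen` -- curative-intent post-surgical chemotherapy (for
#'   example the doxorubicin/cyclophosphamide "AC" combination), which has
#'   no palliative role.
#'
#' Roles are not mutually exclusive. Lookup is case-insensitive and
#' whitespace-insensitive, and whole-combination entries (keys joining
#' several drug names with `+`) are matched against the joined drug list of
#' a claim in addition to per-drug matching, because a named combination can
#' carry roles its components alone do not.
#'
#' @name drug_catalog
NULL

drug_roles <- function() {
  c("first_line_palliative", "second_line_palliative",
    "non_chemotherapy", "adjuvant_regimen")
}

# Lookup normalization: case-fold and drop all whitespace, so
# "Adriamycin + Cyclophosphamide" and "adriamycin+cyclophosphamide" agree.
normalize_drug_name <- function(x) {
  gsub("[[:space:]]+", "", tolower(x))
}

new_drug_catalog <- function(entries, source) {
  stopifnot(is.list(entries), is.character(source), length(source) == 1L)
  structure(list(entries = entries, source = source), class = "drug_catalog")
}

#' Load a drug-role catalog from a YAML config file
#'
#' The config file has a free-text `source` field (provenance of the drug
#' list) and a `drugs` mapping from drug-or-regimen name to a list of role
#' strings. Every entry must carry at least one valid role (see
#' [drug_catalog]). The package ships a default catalog at
#' `system.file("extdata", "default_catalog.yaml", package = "palliaudit")`;
#' its drug list is a package-authored illustrative stand-in for a
#' guideline-issued list and is meant to be replaced by the user's
#' authoritative catalog in real audits.
#'
#' @param path path to a YAML catalog file; defaults to the shipped catalog.
#' @return a `drug_catalog` object.
#' @examples
#' cat <- load_catalog()
#' classify_regimen("Tamoxifen", cat)
#' @export
load_catalog <- function(path = system.file("extdata", "default_catalog.yaml",
                                            package = "palliaudit")) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  drugs <- cfg$drugs
  if (is.null(drugs)) drugs <- list()
  entries <- list()
  for (nm in names(drugs)) {
    roles <- unlist(drugs[[nm]])
    bad <- setdiff(roles, drug_roles())
    if (length(bad)) {
      stop("catalog entry '", nm, "' has unknown role(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (length(roles) == 0L) {
      stop("catalog entry '", nm, "' has an empty role set", call. = FALSE)
    }
    entries[[normalize_drug_name(nm)]] <- unique(roles)
  }
  src <- cfg$source
  if (is.null(src)) src <- paste0("loaded from ", path)
  new_drug_catalog(entries, as.character(src)[1])
}

#' Classify an administered regimen into guideline roles
#'
#' Looks up each drug name and, additionally, the whole joined regimen
#' string (both in given order and with drug tokens sorted) in the catalog,
#' and returns the union of matched role sets together with the list of
#' drugs that matched nothing. The classification is a statement of catalog
#' facts only; precedence between roles is the audit engine's concern.
#'
#' @param drugs character vector of drug names (a claim's administered
#'   list), or a single semicolon-delimited string.
#' @param catalog a `drug_catalog` from [load_catalog()].
#' @return a list of class `regimen_classification` with elements `roles`
#'   (character subset of the four roles), `unclassified_drugs` (character),
#'   and `pure_non_chemotherapy` (`TRUE` when at least one drug matched and
#'   every matched role is `non_chemotherapy`).
#' @export
classify_regimen <- function(drugs, catalog) {
  stopifnot(inherits(catalog, "drug_catalog"))
  if (length(drugs) == 1L && grepl(";", drugs, fixed = TRUE)) {
    drugs <- strsplit(drugs, ";", fixed = TRUE)[[1]]
  }
  drugs <- trimws(drugs)
  drugs <- drugs[nzchar(drugs)]
  keys <- normalize_drug_name(drugs)
  roles <- character()
  unclassified <- character()
  for (i in seq_along(keys)) {
    hit <- catalog$entries[[keys[i]]]
    if (is.null(hit)) {
      unclassified <- c(unclassified, drugs[i])
    } else {
      roles <- c(roles, hit)
    }
  }
  if (length(keys) > 1L) {
    for (joined in unique(c(paste(keys, collapse = "+"),
                            paste(sort(keys), collapse = "+")))) {
      hit <- catalog$entries[[joined]]
      if (!is.null(hit)) roles <- c(roles, hit)
    }
  }
  roles <- sort(unique(roles))
  structure(
    list(
      roles = roles,
      unclassified_drugs = unclassified,
      pure_non_chemotherapy = length(roles) > 0L &&
        identical(roles, "non_chemotherapy")
    ),
    class = "regimen_classification"
  )
}

# First catalog entry (in file order) whose role set is exactly `role`;
# used by the synthetic generator to pick a representative drug per role.
role_exemplar <- function(catalog, role) {
  for (nm in names(catalog$entries)) {
    if (identical(catalog$entries[[nm]], role)) {
      return(nm)
    }
  }
  stop("catalog has no entry with exactly role '", role, "'", call. = FALSE)
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("<drug_catalog> ", length(x$entries), " entr",
      if (length(x$entries) == 1L) "y" else "ies", "\n", sep = "")
  cat("source:", x$source, "\n")
  invisible(x)
}

#' @export
print.regimen_classification <- function(x, ...) {
  cat("roles:",
      if (length(x$roles)) paste(x$roles, collapse = ", ") else "(none)",
      "\n")
  if (length(x$unclassified_drugs)) {
    cat("unclassified:", paste(x$unclassified_drugs, collapse = ", "), "\n")
  }
  invisible(x)
}
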