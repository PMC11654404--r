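#' Reason codes for audit determinations
#'
#' Every audited claim receives exactly one reason code, and the code's
#' prefix fixes the package-selection determination: `CA_*` codes mean the
#' package selection cannot be assessed, `IN_*` codes mean it was
#' inappropriate, `AP_*` codes mean it was appropriate.
#'
#' @return a data frame with columns `reason` (code), `package_determination`,
#'   and `description`.
#' @export
reason_codes <- function() {
  data.frame(
    reason = c(
      "CA_NO_BIOPSY", "CA_NO_MET_NO_GAP", "CA_REGIMEN_DISCREPANCY",
      "IN_NO_MET_WITHIN_6MO", "IN_NON_BREAST_DX", "IN_NON_CHEMO_DRUGS",
      "IN_NO_PALLIATIVE_ROLE",
      "AP_FIRST_LINE", "AP_SECOND_LINE_WITH_FIRST_DOC",
      "AP_SECOND_LINE_NO_FIRST_DOC"
    ),
    package_determination = c(
      rep("cannot_assess", 3), rep("inappropriate", 4), rep("appropriate", 3)
    ),
    description = c(
      "Biopsy/FNAC report unavailable",
      "No documentation of metastasis and no surgery date to compute a gap",
      "Discrepancy between consent-form regimen and clinical notes",
      "No documented metastasis; chemotherapy within 6 months of surgery",
      "Biopsy showed a variant breast condition or a non-breast cancer",
      "Only non-chemotherapy drugs administered",
      "Chemotherapy regimen holds no palliative guideline role",
      "First-line palliative chemotherapy in an established palliative context",
      "Second-line palliative chemotherapy, prior first-line documented",
      "Second-line palliative chemotherapy, prior first-line not documented"
    ),
    stringsAsFactors = FALSE
  )
}

determination_for_reason <- function(reason) {
  rc <- reason_codes()
  rc$package_determination[match(reason, rc$reason)]
}

# Regimen-string normalization for the consent-vs-notes comparison:
# case-fold, strip non-alphanumerics within tokens, split combination
# strings on +/,;/ separators, sort the drug tokens. "AC" formatting
# variants and token order never produce a spurious discrepancy.
normalize_regimen_string <- function(x) {
  vapply(x, function(s) {
    toks <- strsplit(tolower(s), "[+,/;&]")[[1]]
    toks <- gsub("[^a-z0-9]", "", toks)
    toks <- toks[nzchar(toks)]
    paste(sort(toks), collapse = "+")
  }, character(1), USE.NAMES = FALSE)
}

#' Is the palliative context established for a claim?
#'
#' Palliative chemotherapy is indicated for metastatic disease. The context
#' is `"established"` when metastasis is documented or the
#' surgery-to-chemotherapy gap exceeds six calendar months;
#' `"not_established"` when there is no metastasis documentation and the
#' gap is six months or less (read as indicative of non-metastatic,
#' adjuvant-setting disease); `"unknown"` when there is neither metastasis
#' documentation nor a surgery date from which to compute a gap.
#'
#' @param metastasis_documented `"yes"` or `"no_documentation"` (vector).
#' @param gap `"yes"`, `"no"`, or `"unknown"` from
#'   [gap_exceeds_six_months()] (vector).
#' @return character vector over `{"established", "not_established",
#'   "unknown"}`.
#' @export
establish_palliative_context <- function(metastasis_documented, gap) {
  stopifnot(all(metastasis_documented %in% c("yes", "no_documentation")),
            all(gap %in% c("yes", "no", "unknown")))
  ifelse(metastasis_documented == "yes" | gap == "yes", "established",
         ifelse(gap == "no", "not_established", "unknown"))
}

#' Audit a single claim
#'
#' Applies the guideline-derived decision sequence to one claim and returns
#' the package-selection determination, the treatment determination, the
#' reason code, and the full evidence trail (every rule evaluated, in
#' order). The rules are applied in a fixed order and the first that fires
#' decides the reason:
#'
#' 1. no biopsy/FNAC report -> `CA_NO_BIOPSY`;
#' 2. consent-form and clinical-notes regimens both present but discrepant
#'    after normalization -> `CA_REGIMEN_DISCREPANCY`;
#' 3. biopsy diagnosis is a variant breast condition or a non-breast
#'    cancer -> `IN_NON_BREAST_DX`;
#' 4. palliative context unknown (no metastasis documentation, no surgery
#'    date) -> `CA_NO_MET_NO_GAP`;
#' 5. palliative context not established (chemo within six months of
#'    surgery, no metastasis documentation) -> `IN_NO_MET_WITHIN_6MO`;
#' 6. regimen is purely non-chemotherapy -> `IN_NON_CHEMO_DRUGS`;
#' 7. regimen holds a first-line palliative role -> `AP_FIRST_LINE`;
#' 8. regimen holds a second-line palliative role ->
#'    `AP_SECOND_LINE_WITH_FIRST_DOC` or `AP_SECOND_LINE_NO_FIRST_DOC`
#'    depending on prior first-line documentation;
#' 9. otherwise (chemotherapy with no palliative guideline role despite an
#'    established palliative context) -> `IN_NO_PALLIATIVE_ROLE`.
#'
#' Document-sufficiency checks precede clinical checks so that each claim
#' gets a single, reproducible reason even when several criteria apply.
#'
#' The treatment determination is `appropriate` for `AP_FIRST_LINE` and
#' `AP_SECOND_LINE_WITH_FIRST_DOC`; `inappropriate` when rule 9 fires or
#' when the claim's expert-review override flag is set on an
#' inappropriate-package claim; and `cannot_assess` otherwise (including
#' every `CA_*` claim and second-line claims without documented first-line
#' therapy, where the record is insufficient to judge the care).
#'
#' @param claim a one-row [claims_cohort()] (or a single [claim_record()]).
#' @param catalog a `drug_catalog` from [load_catalog()].
#' @return a list of class `claim_audit` with elements `claim_id`,
#'   `package_determination`, `treatment_determination`, `reason`,
#'   `gap_exceeds_6_months`, and `evidence` (data frame of rule/outcome
#'   pairs in evaluation order).
#' @export
audit_claim <- function(claim, catalog) {
  claim <- claims_cohort(claim)
  if (nrow(claim) != 1L) {
    stop("audit_claim() takes a single claim; use audit_cohort() for many",
         call. = FALSE)
  }
  rules <- character()
  outcomes <- character()
  note <- function(rule, outcome) {
    rules[[length(rules) + 1L]] <<- rule
    outcomes[[length(outcomes) + 1L]] <<- outcome
  }
  gap <- gap_exceeds_six_months(claim$surgery_date, claim$chemo_claim_date)

  reason <- NULL
  repeat {
    ba <- biopsy_available(claim)
    note("biopsy_or_fnac_available", if (ba) "yes" else "no")
    if (!ba) {
      reason <- "CA_NO_BIOPSY"
      break
    }
    comparable <- !is.na(claim$regimen_on_consent) &&
      !is.na(claim$regimen_in_notes)
    discrepant <- comparable &&
      normalize_regimen_string(claim$regimen_on_consent) !=
        normalize_regimen_string(claim$regimen_in_notes)
    note("regimen_consent_vs_notes",
         if (!comparable) "not_comparable"
         else if (discrepant) "discrepant" else "concordant")
    if (discrepant) {
      reason <- "CA_REGIMEN_DISCREPANCY"
      break
    }
    note("biopsy_diagnosis", claim$biopsy_diagnosis)
    if (claim$biopsy_diagnosis %in%
          c("variant_breast_condition", "other_cancer")) {
      reason <- "IN_NON_BREAST_DX"
      break
    }
    ctx <- establish_palliative_context(claim$metastasis_documented, gap)
    note("gap_exceeds_six_months", gap)
    note("palliative_context", ctx)
    if (ctx == "unknown") {
      reason <- "CA_NO_MET_NO_GAP"
      break
    }
    if (ctx == "not_established") {
      reason <- "IN_NO_MET_WITHIN_6MO"
      break
    }
    cls <- classify_regimen(claim$drugs, catalog)
    note("regimen_roles",
         if (length(cls$roles)) paste(cls$roles, collapse = ",") else "(none)")
    if (cls$pure_non_chemotherapy) {
      reason <- "IN_NON_CHEMO_DRUGS"
      break
    }
    if ("first_line_palliative" %in% cls$roles) {
      reason <- "AP_FIRST_LINE"
      break
    }
    if ("second_line_palliative" %in% cls$roles) {
      note("prior_first_line_documented",
           if (claim$prior_first_line_documented) "yes" else "no")
      reason <- if (claim$prior_first_line_documented) {
        "AP_SECOND_LINE_WITH_FIRST_DOC"
      } else {
        "AP_SECOND_LINE_NO_FIRST_DOC"
      }
      break
    }
    note("no_palliative_role_fallthrough", "fired")
    reason <- "IN_NO_PALLIATIVE_ROLE"
    break
  }

  pkg <- determination_for_reason(reason)
  treat <- if (startsWith(reason, "CA_") ||
                 reason == "AP_SECOND_LINE_NO_FIRST_DOC") {
    "cannot_assess"
  } else if (reason == "IN_NO_PALLIATIVE_ROLE") {
    "inappropriate"
  } else if (claim$treatment_override_inappropriate &&
               startsWith(reason, "IN_")) {
    "inappropriate"
  } else if (reason %in% c("AP_FIRST_LINE", "AP_SECOND_LINE_WITH_FIRST_DOC")) {
    "appropriate"
  } else {
    "cannot_assess"
  }
  if (claim$treatment_override_inappropriate && startsWith(reason, "IN_")) {
    note("expert_override_inappropriate_treatment", "applied")
  }

  structure(
    list(
      claim_id = claim$claim_id,
      package_determination = pkg,
      treatment_determination = treat,
      reason = reason,
      gap_exceeds_6_months = gap,
      evidence = data.frame(rule = rules, outcome = outcomes,
                            stringsAsFactors = FALSE)
    ),
    class = "claim_audit"
  )
}

#' Audit every claim in a cohort
#'
#' Runs [audit_claim()] over a cohort and collects the verdicts into one
#' data frame, with the per-claim evidence trails attached.
#'
#' @param cohort a [claims_cohort()].
#' @param catalog a `drug_catalog` from [load_catalog()].
#' @return a data frame of class `audit_results` with columns `claim_id`,
#'   `sector`, `package_determination`, `treatment_determination`, `reason`,
#'   `gap_exceeds_6_months`, and an `evidence` attribute: a named list (by
#'   claim id) of rule/outcome data frames.
#' @examples
#' fix <- build_table2_fixture()
#' res <- audit_cohort(fix, load_catalog())
#' table(res$package_determination)
#' @export
audit_cohort <- function(cohort, catalog) {
  cohort <- claims_cohort(cohort)
  if (nrow(cohort) == 0L) {
    out <- data.frame(
      claim_id = character(), sector = character(),
      package_determination = character(),
      treatment_determination = character(),
      reason = character(), gap_exceeds_6_months = character(),
      stringsAsFactors = FALSE
    )
    attr(out, "evidence") <- list()
    class(out) <- c("audit_results", "data.frame")
    return(out)
  }
  audits <- lapply(seq_len(nrow(cohort)), function(i) {
    audit_claim(cohort[i, , drop = FALSE], catalog)
  })
  out <- data.frame(
    claim_id = vapply(audits, `[[`, "", "claim_id"),
    sector = cohort$sector,
    package_determination = vapply(audits, `[[`, "", "package_determination"),
    treatment_determination =
      vapply(audits, `[[`, "", "treatment_determination"),
    reason = vapply(audits, `[[`, "", "reason"),
    gap_exceeds_6_months = vapply(audits, `[[`, "", "gap_exceeds_6_months"),
    stringsAsFactors = FALSE
  )
  attr(out, "evidence") <- setNames(lapply(audits, `[[`, "evidence"),
                                    out$claim_id)
  class(out) <- c("audit_results", "data.frame")
  out
}

#' @export
print.claim_audit <- function(x, ...) {
  cat("<claim_audit> ", x$claim_id, "\n", sep = "")
  cat("  package:   ", x$package_determination, "\n", sep = "")
  cat("  treatment: ", x$treatment_determination, "\n", sep = "")
  cat("  reason:    ", x$reason, "\n", sep = "")
  cat("  gap > 6 months: ", x$gap_exceeds_6_months, "\n", sep = "")
  cat("  evidence:\n")
  for (i in seq_len(nrow(x$evidence))) {
    cat("    ", x$evidence$rule[i], " = ", x$evidence$outcome[i], "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.audit_results <- function(x, ...) {
  cat("<audit_results> ", nrow(x), " claim(s)\n", sep = "")
  if (nrow(x)) {
    print(table(package = x$package_determination,
                treatment = x$treatment_determination))
  }
  invisible(x)
}
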