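test_that("palliative context follows metastasis documentation and the gap", {
  expect_equal(establish_palliative_context("yes", "unknown"), "established")
  expect_equal(establish_palliative_context("no_documentation", "no"),
               "not_established")
  expect_equal(establish_palliative_context("no_documentation", "unknown"),
               "unknown")
  expect_equal(establish_palliative_context("no_documentation", "yes"),
               "established")
})

test_that("audit_claim reproduces the documented single-claim verdicts", {
  cat <- micro_catalog()
  verdict <- function(claim) {
    a <- audit_claim(claim, cat)
    c(a$package_determination, a$treatment_determination, a$reason)
  }
  # metastatic disease documented, first-line regimen
  expect_equal(
    verdict(claim_record(metastasis_documented = "yes", drugs = "aaa")),
    c("appropriate", "appropriate", "AP_FIRST_LINE")
  )
  # no metastasis documentation, chemo 2 months after surgery, adjuvant drugs
  expect_equal(
    verdict(claim_record(surgery_type = "MRM",
                         surgery_date = as.Date("2019-06-01"),
                         chemo_claim_date = as.Date("2019-08-01"),
                         drugs = "ddd")),
    c("inappropriate", "cannot_assess", "IN_NO_MET_WITHIN_6MO")
  )
  # consent form and notes disagree on the regimen
  expect_equal(
    verdict(claim_record(metastasis_documented = "yes", drugs = "aaa",
                         regimen_on_consent = "AC",
                         regimen_in_notes = "paclitaxel")),
    c("cannot_assess", "cannot_assess", "CA_REGIMEN_DISCREPANCY")
  )
  # hormonal-therapy-only regimen in an established palliative context
  expect_equal(
    verdict(claim_record(metastasis_documented = "yes", drugs = "ccc")),
    c("inappropriate", "cannot_assess", "IN_NON_CHEMO_DRUGS")
  )
  # second-line drugs without documented first-line therapy
  expect_equal(
    verdict(claim_record(metastasis_documented = "yes", drugs = "bbb")),
    c("appropriate", "cannot_assess", "AP_SECOND_LINE_NO_FIRST_DOC")
  )
  # same with prior first-line documented
  expect_equal(
    verdict(claim_record(metastasis_documented = "yes", drugs = "bbb",
                         prior_first_line_documented = TRUE)),
    c("appropriate", "appropriate", "AP_SECOND_LINE_WITH_FIRST_DOC")
  )
  # missing tissue diagnosis trumps everything
  expect_equal(
    verdict(claim_record(documents = c("invoice", "consent_form"),
                         metastasis_documented = "yes", drugs = "aaa")),
    c("cannot_assess", "cannot_assess", "CA_NO_BIOPSY")
  )
})

test_that("regimen normalization prevents spurious discrepancies", {
  cat <- micro_catalog()
  a <- audit_claim(
    claim_record(metastasis_documented = "yes", drugs = "aaa",
                 regimen_on_consent = "Paclitaxel + Carboplatin",
                 regimen_in_notes = "carboplatin, PACLITAXEL"),
    cat
  )
  expect_false(a$reason == "CA_REGIMEN_DISCREPANCY")
})

# Independent decision-table oracle over the abstract discrete inputs.
oracle_verdict <- function(ba, disc, dx, met, gap, profile, prior, override) {
  reason <-
    if (!ba) "CA_NO_BIOPSY"
    else if (disc == "both_diff") "CA_REGIMEN_DISCREPANCY"
    else if (dx %in% c("variant_breast_condition", "other_cancer")) {
      "IN_NON_BREAST_DX"
    } else {
      ctx <- if (met == "yes" || gap == "yes") "established"
             else if (gap == "no") "not_established" else "unknown"
      if (ctx == "unknown") "CA_NO_MET_NO_GAP"
      else if (ctx == "not_established") "IN_NO_MET_WITHIN_6MO"
      else if (profile == "nonchemo") "IN_NON_CHEMO_DRUGS"
      else if (profile %in% c("first", "first_and_second")) "AP_FIRST_LINE"
      else if (profile == "second") {
        if (prior) "AP_SECOND_LINE_WITH_FIRST_DOC"
        else "AP_SECOND_LINE_NO_FIRST_DOC"
      } else "IN_NO_PALLIATIVE_ROLE"
    }
  pkg <- c(CA = "cannot_assess", IN = "inappropriate",
           AP = "appropriate")[[substr(reason, 1, 2)]]
  treat <-
    if (reason == "IN_NO_PALLIATIVE_ROLE") "inappropriate"
    else if (override && pkg == "inappropriate") "inappropriate"
    else if (reason %in% c("AP_FIRST_LINE", "AP_SECOND_LINE_WITH_FIRST_DOC")) {
      "appropriate"
    } else "cannot_assess"
  c(pkg, treat, reason)
}

test_that("engine equals the decision-table oracle on the full input space", {
  cat <- micro_catalog()
  chemo <- as.Date("2019-10-01")
  grid <- expand.grid(
    ba = c(TRUE, FALSE),
    disc = c("both_equal", "both_diff", "consent_missing"),
    dx = c("breast_cancer", "variant_breast_condition", "other_cancer",
           "unknown"),
    met = c("yes", "no_documentation"),
    gap = c("yes", "no", "unknown"),
    profile = c("first", "second", "nonchemo", "adjuvant", "unclassified",
                "first_and_second"),
    prior = c(TRUE, FALSE),
    override = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    drugs <- profile_drugs(g$profile)
    joined <- paste(drugs, collapse = "+")
    claim <- claim_record(
      documents = c("invoice", "checklist_unlisted_palliative",
                    "chemotherapy_details", "consent_form",
                    if (g$ba) "biopsy_report"),
      biopsy_diagnosis = g$dx,
      metastasis_documented = g$met,
      surgery_type = if (g$gap == "unknown") "none_recorded" else "MRM",
      surgery_date = switch(g$gap, yes = chemo - 250, no = chemo - 30,
                            unknown = as.Date(NA)),
      chemo_claim_date = chemo,
      drugs = drugs,
      regimen_on_consent = switch(g$disc, both_equal = joined,
                                  both_diff = "something+else",
                                  consent_missing = NA_character_),
      regimen_in_notes = joined,
      prior_first_line_documented = g$prior,
      treatment_override_inappropriate = g$override
    )
    got <- audit_claim(claim, cat)
    want <- oracle_verdict(g$ba, g$disc, g$dx, g$met, g$gap, g$profile,
                           g$prior, g$override)
    expect_equal(
      c(got$package_determination, got$treatment_determination, got$reason),
      want,
      info = paste(unlist(g), collapse = "|")
    )
  }
})

test_that("reason codes pin the package determination and audits are deterministic", {
  fix <- build_table2_fixture()
  cat <- load_catalog()
  res <- audit_cohort(fix, cat)
  rc <- reason_codes()
  expect_equal(
    res$package_determination,
    rc$package_determination[match(res$reason, rc$reason)]
  )
  res2 <- audit_cohort(fix, cat)
  expect_identical(res, res2)
  a1 <- audit_claim(fix[7, ], cat)
  a2 <- audit_claim(fix[7, ], cat)
  expect_identical(a1$evidence, a2$evidence)
})

test_that("documenting metastasis never worsens assessability", {
  cat <- load_catalog()
  g <- generate_cohort(generator_config(n_patients_per_sector = 100,
                                        seed = 2024))
  res <- audit_cohort(g$cohort, cat)
  idx <- which(res$reason == "IN_NO_MET_WITHIN_6MO")
  expect_gt(length(idx), 0)
  for (i in idx) {
    claim <- as.data.frame(g$cohort)[i, , drop = FALSE]
    claim$metastasis_documented <- "yes"
    a <- audit_claim(claims_cohort(claim), cat)
    expect_false(a$package_determination == "cannot_assess")
    expect_false(a$reason == "CA_NO_MET_NO_GAP")
  }
})

test_that("the evidence trail records the rules in evaluation order", {
  cat <- micro_catalog()
  a <- audit_claim(claim_record(metastasis_documented = "yes", drugs = "aaa",
                                regimen_on_consent = "aaa",
                                regimen_in_notes = "aaa"), cat)
  expect_equal(a$evidence$rule[1], "biopsy_or_fnac_available")
  expect_true("palliative_context" %in% a$evidence$rule)
  expect_equal(a$evidence$rule[nrow(a$evidence)], "regimen_roles")
})
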