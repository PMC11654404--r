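# Synthetic claims: a deterministic fixture that encodes the audited
# cohort's attribute patterns, and a seeded stochastic generator for
# arbitrary cohort sizes. Both realize *clinical attribute patterns* (the
# inputs a reason code requires); the audit engine, not the generator,
# produces the determinations.

# Pattern names are reason codes; the fallthrough pattern also sets the
# expert-review override flag.
pattern_names <- function() {
  reason_codes()$reason
}

# Representative drug names per role, taken from the catalog so fixtures
# track catalog edits. The adjuvant exemplar prefers a named combination
# ("a+b") entry, split into its component drugs.
role_drugs <- function(catalog) {
  adj <- NULL
  for (nm in names(catalog$entries)) {
    if (identical(catalog$entries[[nm]], "adjuvant_regimen") &&
          grepl("+", nm, fixed = TRUE)) {
      adj <- strsplit(nm, "+", fixed = TRUE)[[1]]
      break
    }
  }
  if (is.null(adj)) adj <- role_exemplar(catalog, "adjuvant_regimen")
  list(
    first = role_exemplar(catalog, "first_line_palliative"),
    second = role_exemplar(catalog, "second_line_palliative"),
    non_chemo = role_exemplar(catalog, "non_chemotherapy"),
    adjuvant = adj
  )
}

# Vectorized realization of clinical attributes for assigned patterns.
# `variant` disambiguates under-determined patterns: for the appropriate
# patterns it picks how the palliative context is established ("metastasis"
# or "gap"); for IN_NON_BREAST_DX it picks the diagnosis
# ("variant_breast_condition" or "other_cancer").
realize_claims <- function(pattern, sector, chemo_date, variant, catalog) {
  stopifnot(all(pattern %in% pattern_names()))
  n <- length(pattern)
  rd <- role_drugs(catalog)
  drug_for <- function(p) {
    switch(p,
      IN_NO_MET_WITHIN_6MO = ,
      IN_NON_BREAST_DX = ,
      IN_NO_PALLIATIVE_ROLE = paste(rd$adjuvant, collapse = ";"),
      IN_NON_CHEMO_DRUGS = rd$non_chemo,
      AP_SECOND_LINE_WITH_FIRST_DOC = ,
      AP_SECOND_LINE_NO_FIRST_DOC = rd$second,
      rd$first
    )
  }
  drugs <- vapply(pattern, drug_for, "", USE.NAMES = FALSE)

  gap_context <- pattern %in% c("AP_FIRST_LINE", "AP_SECOND_LINE_WITH_FIRST_DOC",
                                "AP_SECOND_LINE_NO_FIRST_DOC",
                                "IN_NON_CHEMO_DRUGS", "IN_NO_PALLIATIVE_ROLE") &
    variant == "gap"
  met <- ifelse(pattern %in% c("IN_NO_MET_WITHIN_6MO", "CA_NO_MET_NO_GAP") |
                  gap_context, "no_documentation", "yes")
  # within-6-months claims: surgery 60 days before chemo; beyond-6-months
  # context: 300 days (always past the clamped 6-calendar-month anniversary)
  surgery_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  within <- pattern == "IN_NO_MET_WITHIN_6MO"
  surgery_date[within] <- chemo_date[within] - 60L
  surgery_date[gap_context] <- chemo_date[gap_context] - 300L
  has_surgery <- !is.na(surgery_date)
  surgery_type <- ifelse(has_surgery,
                         ifelse(seq_len(n) %% 2L == 0L, "BCS", "MRM"),
                         "none_recorded")

  dx <- ifelse(pattern == "IN_NON_BREAST_DX",
               ifelse(variant == "other_cancer", "other_cancer",
                      "variant_breast_condition"),
               "breast_cancer")

  joined <- gsub(";", "+", drugs, fixed = TRUE)
  consent <- joined
  notes <- joined
  disc <- pattern == "CA_REGIMEN_DISCREPANCY"
  consent[disc] <- paste(rd$adjuvant, collapse = "+")

  out <- data.frame(
    sector = sector,
    package_code = "PC-UNLISTED",
    stringsAsFactors = FALSE
  )
  for (doc in document_types()) {
    out[[doc]] <- doc %in% c("invoice", "checklist_unlisted_palliative",
                             "chemotherapy_details", "preauthorization_form",
                             "consent_form")
  }
  out$biopsy_report <- pattern != "CA_NO_BIOPSY"
  out$fnac_report <- FALSE
  out$biopsy_diagnosis <- dx
  out$metastasis_documented <- met
  out$surgery_type <- surgery_type
  out$surgery_date <- surgery_date
  out$chemo_claim_date <- chemo_date
  out$drugs <- drugs
  out$regimen_on_consent <- consent
  out$regimen_in_notes <- notes
  out$prior_first_line_documented <- pattern == "AP_SECOND_LINE_WITH_FIRST_DOC"
  out$treatment_override_inappropriate <- pattern == "IN_NO_PALLIATIVE_ROLE"
  out
}

#' Deterministic 50-claim audit fixture
#'
#' Builds, with no randomness, a 50-claim cohort (25 public, 25 private)
#' whose clinical attribute patterns and document-availability flags encode
#' the audited study cohort: each reason-pattern occurs exactly as often,
#' and with the same sector split, as in the published determinations, and
#' the document flags reproduce every cell of the published
#' document-availability table (including the derived any-radiodiagnosis
#' count). The fixture stores only *inputs* -- running [audit_cohort()] on
#' it produces the determinations.
#'
#' Pattern counts (public/private): regimen discrepancy 2 (2/0); no
#' metastasis documentation and no computable gap 3 (0/3); chemo within six
#' months of surgery 21 (7/14); non-breast diagnosis 2 (1/1);
#' non-chemotherapy drugs 4 (4/0); chemotherapy without palliative role with
#' expert override 3 (0/3); first-line appropriate 7 (4/3); second-line with
#' documented first-line 2 (2/0); second-line without documented first-line
#' 6 (5/1). The sector split of the override pattern is not printed in the
#' source table; it is forced to private by the printed public column
#' summing to 25 already.
#'
#' @param catalog a `drug_catalog`; fixture drug names are taken from it by
#'   role, so the fixture tracks catalog edits.
#' @return a 50-row [claims_cohort()].
#' @examples
#' fix <- build_table2_fixture()
#' table(fix$sector)
#' @export
build_table2_fixture <- function(catalog = load_catalog()) {
  pub_patterns <- c(
    rep("CA_REGIMEN_DISCREPANCY", 2),
    rep("IN_NO_MET_WITHIN_6MO", 7),
    "IN_NON_BREAST_DX",
    rep("IN_NON_CHEMO_DRUGS", 4),
    rep("AP_SECOND_LINE_NO_FIRST_DOC", 5),
    rep("AP_FIRST_LINE", 4),
    rep("AP_SECOND_LINE_WITH_FIRST_DOC", 2)
  )
  pri_patterns <- c(
    rep("CA_NO_MET_NO_GAP", 3),
    rep("IN_NO_MET_WITHIN_6MO", 14),
    "IN_NON_BREAST_DX",
    rep("IN_NO_PALLIATIVE_ROLE", 3),
    "AP_SECOND_LINE_NO_FIRST_DOC",
    rep("AP_FIRST_LINE", 3)
  )
  pattern <- c(pub_patterns, pri_patterns)
  sector <- rep(c("public", "private"), each = 25L)

  variant <- rep("metastasis", 50L)
  variant[10] <- "variant_breast_condition"   # public non-breast claim
  variant[25 + 18] <- "other_cancer"          # private non-breast claim
  # exercise both context routes in the appropriate rows
  variant[c(22, 23)] <- "gap"                 # public first-line via gap
  variant[25 + c(24, 25)] <- "gap"            # private first-line via gap
  variant[c(18, 19)] <- "gap"                 # public 2nd-line-no-doc via gap

  chemo_date <- as.Date("2019-06-01") + (seq_len(50L) - 1L) * 3L
  claims <- realize_claims(pattern, sector, chemo_date, variant, catalog)

  idx <- function(i) seq_len(25L) %in% i
  doc_sets <- list(
    public = list(
      invoice = 1:25, checklist_unlisted_palliative = 1:25,
      chemotherapy_details = 1:25, preauthorization_form = 1:25,
      consent_form = (1:25)[-3], biopsy_report = 1:25,
      cbc_report = 1:23, biochemistry_report = 1:20,
      registration_form = 1:19, ultrasound_report = 1:8,
      ct_scan_report = 7:13, counselling_form = 1:5,
      fnac_report = integer(), ration_card = 1:4, chest_xray = 1:3
    ),
    private = list(
      invoice = 1:25, checklist_unlisted_palliative = 1:25,
      chemotherapy_details = 1:25, preauthorization_form = 1:24,
      consent_form = 1:25, biopsy_report = 3:25,
      cbc_report = integer(), biochemistry_report = integer(),
      registration_form = integer(), ultrasound_report = 1,
      ct_scan_report = integer(), counselling_form = integer(),
      fnac_report = 1:5, ration_card = integer(), chest_xray = integer()
    )
  )
  for (sec in c("public", "private")) {
    rows <- which(sector == sec)
    for (doc in document_types()) {
      claims[rows, doc] <- idx(doc_sets[[sec]][[doc]])
    }
  }
  # no consent form filed -> no consent regimen string to compare
  no_consent <- !claims$consent_form
  claims$regimen_on_consent[no_consent] <- NA_character_

  tag <- sprintf("%s-%02d", toupper(substr(sector, 1, 3)),
                 c(seq_len(25L), seq_len(25L)))
  claims <- cbind(
    data.frame(
      claim_id = paste0("CLM-", tag),
      patient_id = paste0("PT-", tag),
      hospital_id = ifelse(sector == "public", "HOSP-PUB", "HOSP-PRI"),
      stringsAsFactors = FALSE
    ),
    claims
  )
  claims_cohort(claims)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the generator's parameters. Defaults emulate the
#' audited study cohort: 25 patients per sector; the reason-pattern mix at
#' the audited cohort's frequencies; document-availability rates at the
#' published per-sector rates; claims histories with a mean of 14.7 claims
#' per patient and pooled same-hospital claim shares of 0.80 (public) and
#' 0.96 (private), with up to 3 distinct hospitals per patient.
#'
#' @param n_patients_per_sector patients sampled per hospital sector.
#' @param reason_mix named numeric over the reason-pattern codes (see
#'   [reason_codes()]). Interpreted as exact per-cohort counts when the
#'   values are whole numbers summing to the cohort size, otherwise as
#'   probabilities (normalized to 1) sampled independently per claim.
#' @param doc_rates data frame with columns `document`, `public`, `private`
#'   giving per-sector presence probabilities for the unconstrained
#'   document flags; defaults to [default_doc_rates()].
#' @param mean_claims_per_patient mean claims per patient in the generated
#'   history (the index claim counts as one).
#' @param same_hospital_share named numeric (`public`, `private`):
#'   probability that a non-index history claim originates from the index
#'   hospital.
#' @param max_distinct_hospitals cap on distinct hospitals per patient.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_patients_per_sector = 25L,
                             reason_mix = default_reason_mix(),
                             doc_rates = default_doc_rates(),
                             mean_claims_per_patient = 14.7,
                             same_hospital_share = c(public = 0.80,
                                                     private = 0.96),
                             max_distinct_hospitals = 3L,
                             seed = 1L) {
  n_patients_per_sector <- as.integer(n_patients_per_sector)
  stopifnot(n_patients_per_sector >= 0L,
            mean_claims_per_patient >= 1,
            max_distinct_hospitals >= 1L,
            all(c("public", "private") %in% names(same_hospital_share)),
            all(same_hospital_share >= 0 & same_hospital_share <= 1))
  bad <- setdiff(names(reason_mix), pattern_names())
  if (length(bad)) {
    stop("unknown reason pattern(s) in reason_mix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(reason_mix < 0)) {
    stop("reason_mix values must be non-negative", call. = FALSE)
  }
  n_total <- 2L * n_patients_per_sector
  counts_mode <- all(reason_mix == round(reason_mix)) && sum(reason_mix) > 0 &&
    isTRUE(all.equal(sum(reason_mix), n_total))
  if (all(reason_mix == round(reason_mix)) && sum(reason_mix) > n_total) {
    stop("infeasible reason_mix: counts sum to ", sum(reason_mix),
         " but the cohort has ", n_total, " claims", call. = FALSE)
  }
  if (!counts_mode) {
    if (sum(reason_mix) <= 0) {
      stop("reason_mix must have positive mass", call. = FALSE)
    }
    reason_mix <- reason_mix / sum(reason_mix)
  }
  structure(
    list(
      n_patients_per_sector = n_patients_per_sector,
      reason_mix = reason_mix,
      counts_mode = counts_mode,
      doc_rates = doc_rates,
      mean_claims_per_patient = mean_claims_per_patient,
      same_hospital_share = same_hospital_share,
      max_distinct_hospitals = as.integer(max_distinct_hospitals),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @export
default_reason_mix <- function() {
  c(
    CA_NO_BIOPSY = 0,
    CA_NO_MET_NO_GAP = 3 / 50,
    CA_REGIMEN_DISCREPANCY = 2 / 50,
    IN_NO_MET_WITHIN_6MO = 21 / 50,
    IN_NON_BREAST_DX = 2 / 50,
    IN_NON_CHEMO_DRUGS = 4 / 50,
    IN_NO_PALLIATIVE_ROLE = 3 / 50,
    AP_FIRST_LINE = 7 / 50,
    AP_SECOND_LINE_WITH_FIRST_DOC = 2 / 50,
    AP_SECOND_LINE_NO_FIRST_DOC = 6 / 50
  )
}

#' @rdname generator_config
#' @export
default_doc_rates <- function() {
  data.frame(
    document = document_types(),
    public = c(25, 25, 25, 25, 24, 25, 23, 20, 19, 8, 7, 5, 0, 4, 3) / 25,
    private = c(25, 25, 25, 24, 25, 23, 0, 0, 0, 1, 0, 0, 5, 0, 0) / 25,
    stringsAsFactors = FALSE
  )
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic claims cohort with histories
#'
#' Draws a cohort of claims whose clinical attributes realize the
#' configured reason-pattern mix, with document flags drawn at the
#' configured per-sector rates (subject to pattern consistency: the
#' tissue-diagnosis and consent-form flags are forced where a pattern
#' requires them), plus a claims history per patient. Identical
#' configuration (including seed) yields identical output.
#'
#' The central correctness property: running [audit_cohort()] on the
#' generated claims returns, for every claim, exactly the reason pattern
#' the generator assigned to it.
#'
#' @param config a [generator_config()].
#' @return list with elements `cohort` (a [claims_cohort()]) and `history`
#'   (a data frame of `patient_id`, `claim_id`, `hospital_id`,
#'   `claim_date`), plus the per-claim `assigned_pattern` attribute on the
#'   cohort.
#' @examples
#' g <- generate_cohort(generator_config(n_patients_per_sector = 10, seed = 7))
#' table(attr(g$cohort, "assigned_pattern"))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_sec <- config$n_patients_per_sector
  n <- 2L * n_sec
  sector <- rep(c("public", "private"), each = n_sec)
  if (n == 0L) {
    empty <- coerce_raw_cohort(empty_raw_cohort())
    attr(empty, "assigned_pattern") <- setNames(character(), character())
    return(list(cohort = empty,
                history = data.frame(patient_id = character(),
                                     claim_id = character(),
                                     hospital_id = character(),
                                     claim_date = as.Date(character()))))
  }
  with_local_seed(config$seed, {
    mix <- config$reason_mix
    pattern <- if (config$counts_mode) {
      sample(rep(names(mix), times = round(mix)))
    } else {
      sample(names(mix), n, replace = TRUE, prob = mix)
    }
    variant <- ifelse(
      pattern == "IN_NON_BREAST_DX",
      sample(c("variant_breast_condition", "other_cancer"), n, replace = TRUE),
      sample(c("metastasis", "gap"), n, replace = TRUE)
    )
    window <- as.Date(c("2019-05-01", "2020-04-01"))
    chemo_date <- window[1] +
      sample.int(as.integer(diff(window)) + 1L, n, replace = TRUE) - 1L
    catalog <- load_catalog()
    claims <- realize_claims(pattern, sector, chemo_date, variant, catalog)

    # draw unconstrained document flags at the configured per-sector rates
    rates <- config$doc_rates
    for (doc in document_types()) {
      p <- ifelse(sector == "public",
                  rates$public[rates$document == doc],
                  rates$private[rates$document == doc])
      claims[[doc]] <- stats::runif(n) < p
    }
    # pattern-consistency constraints on documents
    claims$biopsy_report <- pattern != "CA_NO_BIOPSY" &
      (claims$biopsy_report | !claims$fnac_report)
    claims$fnac_report <- claims$fnac_report & pattern != "CA_NO_BIOPSY"
    claims$consent_form <- claims$consent_form |
      pattern == "CA_REGIMEN_DISCREPANCY"
    claims$regimen_on_consent[!claims$consent_form] <- NA_character_

    tag <- sprintf("%s-%04d", toupper(substr(sector, 1, 3)),
                   c(seq_len(n_sec), seq_len(n_sec)))
    claims <- cbind(
      data.frame(
        claim_id = paste0("CLM-", tag),
        patient_id = paste0("PT-", tag),
        hospital_id = ifelse(sector == "public", "HOSP-PUB", "HOSP-PRI"),
        stringsAsFactors = FALSE
      ),
      claims
    )
    cohort <- claims_cohort(claims)
    attr(cohort, "assigned_pattern") <- setNames(pattern, cohort$claim_id)

    history <- generate_history(cohort, config)
    list(cohort = cohort, history = history)
  })
}

generate_history <- function(cohort, config) {
  hist_window <- as.Date(c("2014-03-19", "2021-03-15"))
  n_alt <- max(config$max_distinct_hospitals - 1L, 0L)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    idx_hosp <- cohort$hospital_id[i]
    share <- config$same_hospital_share[[cohort$sector[i]]]
    n_claims <- 1L + stats::rpois(1L, config$mean_claims_per_patient - 1)
    extra <- n_claims - 1L
    hosp <- rep(idx_hosp, n_claims)
    if (extra > 0L && n_alt > 0L) {
      away <- stats::runif(extra) >= share
      alts <- paste0("ALT-", sample.int(n_alt, extra, replace = TRUE))
      hosp[1L + which(away)] <- alts[away]
    }
    dates <- c(cohort$chemo_claim_date[i],
               hist_window[1] + sample.int(
                 as.integer(diff(hist_window)) + 1L, extra,
                 replace = TRUE) - 1L)
    data.frame(
      patient_id = pid,
      claim_id = c(cohort$claim_id[i],
                   if (extra > 0L) sprintf("%s-H%03d", cohort$claim_id[i],
                                           seq_len(extra))),
      hospital_id = hosp,
      claim_date = dates,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
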