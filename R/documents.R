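#' Supporting-document types for an unlisted palliative chemotherapy claim
#'
#' The claim file submitted for reimbursement can carry up to 15 concrete
#' supporting documents (invoice, scheme checklist, consent form, tissue
#' diagnosis reports, lab reports, radiology reports, ...). A sixteenth,
#' derived category -- any radiodiagnosis -- is true whenever a chest x-ray,
#' CT scan or ultrasound report is present; it is computed on demand and
#' never stored on a claim.
#'
#' @return `document_types()` returns a character vector of the 15 concrete
#'   document codes (these are also the column names used in the cohort
#'   exchange format). `required_documents()` returns the subset that the
#'   scheme marks as required for this package. `radiodiagnosis_components()`
#'   returns the codes whose union defines the derived any-radiodiagnosis
#'   category.
#' @examples
#' document_types()
#' required_documents()
#' @export
document_types <- function() {
  c(
    "invoice",
    "checklist_unlisted_palliative",
    "chemotherapy_details",
    "preauthorization_form",
    "consent_form",
    "biopsy_report",
    "cbc_report",
    "biochemistry_report",
    "registration_form",
    "ultrasound_report",
    "ct_scan_report",
    "counselling_form",
    "fnac_report",
    "ration_card",
    "chest_xray"
  )
}

#' @rdname document_types
#' @export
required_documents <- function() {
  c("checklist_unlisted_palliative", "chemotherapy_details", "biopsy_report")
}

#' @rdname document_types
#' @export
radiodiagnosis_components <- function() {
  c("chest_xray", "ct_scan_report", "ultrasound_report")
}

# Labels used when rendering document tables for people.
document_labels <- function() {
  c(
    invoice = "Invoice (bill)",
    checklist_unlisted_palliative = "Checklist for Unlisted Regimen Palliative Chemotherapy",
    chemotherapy_details = "Chemotherapy details",
    preauthorization_form = "Pre-authorization form",
    consent_form = "Consent form",
    biopsy_report = "Biopsy report",
    cbc_report = "Complete blood count report",
    biochemistry_report = "Biochemistry report",
    registration_form = "Registration form",
    radiodiagnosis_any = "Any radiodiagnosis",
    ultrasound_report = "Ultrasound report",
    ct_scan_report = "CT scan report",
    counselling_form = "Counselling form",
    fnac_report = "Fine needle aspiration cytology (FNAC)",
    ration_card = "Ration card",
    chest_xray = "Chest x-ray"
  )
}
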