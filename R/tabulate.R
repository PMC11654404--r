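#' Tabulate supporting-document availability
#'
#' Catalogues which supporting documents were filed with each index claim
#' and tabulates counts and percentages overall and by hospital sector,
#' including the derived any-radiodiagnosis row (chest x-ray, CT scan
#' and/or ultrasound). Percentages are kept at full precision internally
#' and rendered to whole percent by the print method.
#'
#' @param cohort a [claims_cohort()].
#' @return a data frame of class `doc_availability` with one row per
#'   document type (15 concrete plus `radiodiagnosis_any`), columns
#'   `document`, `label`, `required`, `count_both`, `count_public`,
#'   `count_private`, `percent_both`, `percent_public`, `percent_private`,
#'   sorted by descending `percent_both` (ties broken by document code).
#'   Sector cohort sizes are attached as attributes `n_public` and
#'   `n_private`. Percentages are 0 when the denominator is 0.
#' @export
tabulate_documents <- function(cohort) {
  cohort <- claims_cohort(cohort)
  pub <- cohort$sector == "public"
  n_pub <- sum(pub)
  n_pri <- sum(!pub)
  docs <- document_types()
  present <- as.data.frame(cohort)[, docs, drop = FALSE]
  present$radiodiagnosis_any <-
    Reduce(`|`, present[radiodiagnosis_components()], rep(FALSE, nrow(cohort)))
  all_docs <- c(docs, "radiodiagnosis_any")
  pct <- function(count, n) if (n > 0L) 100 * count / n else 0
  out <- data.frame(
    document = all_docs,
    label = unname(document_labels()[all_docs]),
    required = all_docs %in% required_documents(),
    count_both = vapply(all_docs, function(d) sum(present[[d]]), 0L),
    count_public = vapply(all_docs, function(d) sum(present[[d]][pub]), 0L),
    count_private = vapply(all_docs, function(d) sum(present[[d]][!pub]), 0L),
    stringsAsFactors = FALSE
  )
  out$percent_both <- pct(out$count_both, n_pub + n_pri)
  out$percent_public <- pct(out$count_public, n_pub)
  out$percent_private <- pct(out$count_private, n_pri)
  out <- out[order(-out$percent_both, out$document), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_public") <- n_pub
  attr(out, "n_private") <- n_pri
  class(out) <- c("doc_availability", "data.frame")
  out
}

#' @export
print.doc_availability <- function(x, ...) {
  n <- attr(x, "n_public") + attr(x, "n_private")
  cat("Document availability (", n, " claims: ", attr(x, "n_public"),
      " public, ", attr(x, "n_private"), " private)\n", sep = "")
  shown <- data.frame(
    document = ifelse(x$required, paste0(x$label, " *"), x$label),
    both = x$count_both, public = x$count_public, private = x$count_private,
    pct_both = paste0(round(x$percent_both), "%"),
    pct_public = paste0(round(x$percent_public), "%"),
    pct_private = paste0(round(x$percent_private), "%"),
    stringsAsFactors = FALSE
  )
  print(shown, right = FALSE, row.names = FALSE)
  cat("* required documentation for this package\n")
  invisible(x)
}

#' Summarize audit verdicts over a cohort
#'
#' Aggregates per-claim audit results into the machine-readable audit
#' summary: determination counts, reason-level counts and within-
#' determination percentages, treatment-determination counts, all split by
#' hospital sector, plus the assessable denominator (claims whose package
#' selection could be assessed) and the appropriate share on both the full
#' and the assessable denominators.
#'
#' @param results an `audit_results` data frame from [audit_cohort()].
#' @param cohort the audited [claims_cohort()] (must carry the same claim
#'   ids).
#' @return a list of class `cohort_summary` with elements `n`, `n_public`,
#'   `n_private`, `determinations`, `reasons`, `treatment`,
#'   `assessable_count`, and `appropriate_share_of_assessable` (named
#'   vector: both/public/private, as fractions).
#' @export
summarize_audit <- function(results, cohort) {
  cohort <- claims_cohort(cohort)
  if (!setequal(results$claim_id, cohort$claim_id) ||
        nrow(results) != nrow(cohort)) {
    stop("results and cohort do not carry the same claim ids", call. = FALSE)
  }
  sector <- cohort$sector[match(results$claim_id, cohort$claim_id)]
  pub <- sector == "public"

  count3 <- function(mask) {
    c(both = sum(mask), public = sum(mask & pub), private = sum(mask & !pub))
  }
  dets <- c("appropriate", "inappropriate", "cannot_assess")
  det_counts <- t(vapply(dets, function(d) {
    count3(results$package_determination == d)
  }, c(both = 0, public = 0, private = 0)))
  determinations <- data.frame(
    package_determination = dets,
    count_both = det_counts[, "both"],
    count_public = det_counts[, "public"],
    count_private = det_counts[, "private"],
    stringsAsFactors = FALSE, row.names = NULL
  )

  rc <- reason_codes()
  reason_counts <- t(vapply(rc$reason, function(r) {
    count3(results$reason == r)
  }, c(both = 0, public = 0, private = 0)))
  reasons <- data.frame(
    reason = rc$reason,
    package_determination = rc$package_determination,
    count_both = reason_counts[, "both"],
    count_public = reason_counts[, "public"],
    count_private = reason_counts[, "private"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  det_total <- determinations$count_both[
    match(reasons$package_determination, determinations$package_determination)]
  reasons$percent_of_determination <-
    ifelse(det_total > 0, 100 * reasons$count_both / det_total, 0)

  treat_counts <- t(vapply(dets, function(d) {
    count3(results$treatment_determination == d)
  }, c(both = 0, public = 0, private = 0)))
  treatment <- data.frame(
    treatment_determination = dets,
    count_both = treat_counts[, "both"],
    count_public = treat_counts[, "public"],
    count_private = treat_counts[, "private"],
    stringsAsFactors = FALSE, row.names = NULL
  )

  ca <- results$package_determination == "cannot_assess"
  ap <- results$package_determination == "appropriate"
  assessable <- count3(!ca)
  appropriate <- count3(ap)
  share <- ifelse(assessable > 0, appropriate / assessable, NA_real_)

  structure(
    list(
      n = nrow(cohort),
      n_public = sum(pub),
      n_private = sum(!pub),
      determinations = determinations,
      reasons = reasons,
      treatment = treatment,
      assessable_count = assessable,
      appropriate_share_of_assessable = share
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Audit summary: ", x$n, " claims (", x$n_public, " public, ",
      x$n_private, " private)\n\n", sep = "")
  cat("Package selection:\n")
  print(x$determinations, row.names = FALSE)
  cat("\nReasons (percent within package determination):\n")
  shown <- x$reasons
  shown$percent_of_determination <-
    paste0(round(shown$percent_of_determination), "%")
  print(shown, row.names = FALSE)
  cat("\nTreatment determination:\n")
  print(x$treatment, row.names = FALSE)
  cat("\nAssessable claims: ", x$assessable_count[["both"]], " of ", x$n,
      "\n", sep = "")
  sh <- x$appropriate_share_of_assessable
  cat("Appropriate share of assessable: both ",
      round(100 * sh[["both"]]), "% (public ",
      round(100 * sh[["public"]]), "%, private ",
      round(100 * sh[["private"]]), "%)\n", sep = "")
  invisible(x)
}

#' Claims-history metrics
#'
#' Summarizes where the sampled patients received care under the scheme:
#' the pooled share of their claims that originated from the hospital that
#' generated the index claim, the distribution of distinct hospitals per
#' patient, and the mean number of claims per patient, by sector and
#' overall.
#'
#' @param history a data frame with columns `patient_id`, `claim_id`,
#'   `hospital_id`, `claim_date` (one row per claim in the claims history;
#'   `(patient_id, claim_id)` unique).
#' @param index_claims named character vector mapping `patient_id` to the
#'   hospital that generated the patient's index claim.
#' @param sector_map named character vector mapping `patient_id` to
#'   `"public"`/`"private"`.
#' @return a list of class `history_metrics` with elements `patients` (per
#'   patient: sector, n_claims, n_hospitals, share_index), `by_sector`
#'   (n_patients, n_claims, mean_claims_per_patient,
#'   same_hospital_claim_share — pooled over claims), `overall` (the same,
#'   pooled across sectors), and `distinct_hospitals` (count of patients by
#'   number of distinct hospitals and sector).
#' @export
history_metrics <- function(history, index_claims, sector_map) {
  stopifnot(is.data.frame(history),
            all(c("patient_id", "claim_id", "hospital_id", "claim_date")
                %in% names(history)))
  key <- paste(history$patient_id, history$claim_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, claim_id) in claims history", call. = FALSE)
  }
  missing_idx <- setdiff(unique(history$patient_id), names(index_claims))
  if (length(missing_idx)) {
    stop("patient(s) missing an index hospital: ",
         paste(missing_idx, collapse = ", "), call. = FALSE)
  }
  missing_sec <- setdiff(unique(history$patient_id), names(sector_map))
  if (length(missing_sec)) {
    stop("patient(s) missing a sector: ",
         paste(missing_sec, collapse = ", "), call. = FALSE)
  }
  at_index <- history$hospital_id ==
    unname(index_claims[history$patient_id])
  sector <- unname(sector_map[history$patient_id])

  pts <- unique(history$patient_id)
  patients <- data.frame(
    patient_id = pts,
    sector = unname(sector_map[pts]),
    n_claims = vapply(pts, function(p) sum(history$patient_id == p), 0L),
    n_hospitals = vapply(pts, function(p) {
      length(unique(history$hospital_id[history$patient_id == p]))
    }, 0L),
    share_index = vapply(pts, function(p) {
      m <- history$patient_id == p
      mean(at_index[m])
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )

  sector_stats <- function(mask_claims, mask_patients) {
    data.frame(
      n_patients = sum(mask_patients),
      n_claims = sum(mask_claims),
      mean_claims_per_patient =
        if (sum(mask_patients)) sum(mask_claims) / sum(mask_patients)
        else NA_real_,
      same_hospital_claim_share =
        if (sum(mask_claims)) mean(at_index[mask_claims]) else NA_real_
    )
  }
  by_sector <- do.call(rbind, lapply(c("public", "private"), function(s) {
    cbind(sector = s,
          sector_stats(sector == s, patients$sector == s),
          stringsAsFactors = FALSE)
  }))
  overall <- sector_stats(rep(TRUE, nrow(history)),
                          rep(TRUE, nrow(patients)))

  distinct <- as.data.frame(table(
    n_hospitals = patients$n_hospitals, sector = patients$sector
  ), stringsAsFactors = FALSE)
  names(distinct)[3] <- "n_patients"
  distinct$n_hospitals <- as.integer(distinct$n_hospitals)

  structure(
    list(patients = patients, by_sector = by_sector, overall = overall,
         distinct_hospitals = distinct),
    class = "history_metrics"
  )
}

#' @export
print.history_metrics <- function(x, ...) {
  cat("Claims-history metrics\n")
  print(x$by_sector, row.names = FALSE)
  cat("overall: ", x$overall$n_patients, " patients, ",
      x$overall$n_claims, " claims, mean ",
      round(x$overall$mean_claims_per_patient, 1),
      " claims/patient, same-hospital share ",
      round(100 * x$overall$same_hospital_claim_share), "%\n", sep = "")
  invisible(x)
}
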