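test_that("document tabulation reproduces the fixture's availability table", {
  fix <- build_table2_fixture()
  tab <- tabulate_documents(fix)

  invoice <- tab[tab$document == "invoice", ]
  expect_equal(
    unlist(invoice[c("count_both", "count_public", "count_private")],
           use.names = FALSE),
    c(50, 25, 25)
  )
  expect_equal(
    unlist(invoice[c("percent_both", "percent_public", "percent_private")],
           use.names = FALSE),
    c(100, 100, 100)
  )
  radio <- tab[tab$document == "radiodiagnosis_any", ]
  expect_equal(radio$count_both, 14)
  expect_equal(round(radio$percent_both), 28)
  # rows sorted by descending overall percentage
  expect_true(all(diff(tab$percent_both) <= 0))
  expect_equal(sum(tab$required), 3)
})

test_that("document tabulation of an empty cohort is all zeros", {
  empty <- build_table2_fixture()[0, ]
  tab <- tabulate_documents(empty)
  expect_equal(nrow(tab), 16)
  expect_true(all(tab$count_both == 0))
  expect_true(all(tab$percent_both == 0))
})

test_that("tabulations are invariant under cohort row permutation", {
  fix <- build_table2_fixture()
  set.seed(7)
  shuffled <- claims_cohort(as.data.frame(fix)[sample(nrow(fix)), ])
  expect_equal(as.data.frame(tabulate_documents(shuffled)),
               as.data.frame(tabulate_documents(fix)), ignore_attr = TRUE)

  cat <- load_catalog()
  s1 <- summarize_audit(audit_cohort(fix, cat), fix)
  s2 <- summarize_audit(audit_cohort(shuffled, cat), shuffled)
  expect_equal(s1$determinations, s2$determinations)
  expect_equal(s1$reasons, s2$reasons)
})

test_that("audit summary partitions the cohort and computes sector shares", {
  fix <- build_table2_fixture()
  res <- audit_cohort(fix, load_catalog())
  summ <- summarize_audit(res, fix)
  expect_equal(sum(summ$determinations$count_both), summ$n)
  # reason counts within each determination sum to that determination's count
  by_det <- tapply(summ$reasons$count_both, summ$reasons$package_determination,
                   sum)
  expect_equal(
    as.vector(by_det[summ$determinations$package_determination]),
    summ$determinations$count_both
  )
  expect_equal(unname(summ$assessable_count["both"]),
               summ$n - summ$determinations$count_both[
                 summ$determinations$package_determination == "cannot_assess"])
  expect_equal(unname(summ$appropriate_share_of_assessable["public"]), 11 / 23)
  expect_equal(unname(summ$appropriate_share_of_assessable["private"]), 4 / 22)
})

test_that("audit summary rejects mismatched claim ids and handles one claim", {
  fix <- build_table2_fixture()
  res <- audit_cohort(fix, load_catalog())
  expect_error(summarize_audit(res, fix[-1, ]), "claim ids")

  one <- fix[5, ]
  r1 <- audit_cohort(one, load_catalog())
  s1 <- summarize_audit(r1, one)
  expect_equal(sum(s1$reasons$count_both), 1)
  expect_equal(sum(s1$reasons$count_both > 0), 1)
})

test_that("history metrics match a pencil-and-paper four-patient example", {
  history <- data.frame(
    patient_id = c("A", "A", "A", "B", "C", "C", "C", "C", "C", "D", "D"),
    claim_id = paste0("c", 1:11),
    hospital_id = c("H1", "H1", "H2", "H1", "H3", "H3", "H3", "H4", "H5",
                    "H3", "H4"),
    claim_date = as.Date("2019-01-01") + 1:11,
    stringsAsFactors = FALSE
  )
  index_claims <- c(A = "H1", B = "H1", C = "H3", D = "H3")
  sector_map <- c(A = "public", B = "public", C = "private", D = "private")
  hm <- history_metrics(history, index_claims, sector_map)

  pub <- hm$by_sector[hm$by_sector$sector == "public", ]
  pri <- hm$by_sector[hm$by_sector$sector == "private", ]
  expect_equal(pub$n_claims, 4)
  expect_equal(pub$same_hospital_claim_share, 3 / 4)
  expect_equal(pub$mean_claims_per_patient, 2)
  expect_equal(pri$n_claims, 7)
  expect_equal(pri$same_hospital_claim_share, 4 / 7)
  expect_equal(pri$mean_claims_per_patient, 3.5)
  expect_equal(hm$overall$same_hospital_claim_share, 7 / 11)
  expect_equal(hm$overall$mean_claims_per_patient, 11 / 4)

  pts <- hm$patients
  expect_equal(pts$n_hospitals[pts$patient_id == "C"], 3)
  expect_equal(pts$share_index[pts$patient_id == "B"], 1.0)
  expect_error(history_metrics(history, index_claims[-1], sector_map),
               "missing an index hospital")
})
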