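test_that("the 50-claim fixture is deterministic with the designed structure", {
  f1 <- build_table2_fixture()
  f2 <- build_table2_fixture()
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 50)
  expect_equal(sum(f1$sector == "public"), 25)
  expect_equal(sum(f1$sector == "private"), 25)
  expect_true(all(biopsy_available(f1)))
})

test_that("fixture claims audit to the designed reason patterns", {
  fix <- build_table2_fixture()
  res <- audit_cohort(fix, load_catalog())
  expect_equal(sum(res$reason == "IN_NO_MET_WITHIN_6MO"), 21)
  disc <- res[res$reason == "CA_REGIMEN_DISCREPANCY", ]
  expect_equal(nrow(disc), 2)
  expect_true(all(disc$sector == "public"))
  nogap <- res[res$reason == "CA_NO_MET_NO_GAP", ]
  expect_equal(nrow(nogap), 3)
  expect_true(all(nogap$sector == "private"))
})

test_that("the generator is reproducible and honors degenerate mixes", {
  cfg <- generator_config(n_patients_per_sector = 30, seed = 123)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)

  pure <- generator_config(
    n_patients_per_sector = 20,
    reason_mix = c(AP_FIRST_LINE = 1.0),
    seed = 5
  )
  g <- generate_cohort(pure)
  res <- audit_cohort(g$cohort, load_catalog())
  expect_true(all(res$package_determination == "appropriate"))
  expect_true(all(res$reason == "AP_FIRST_LINE"))
})

test_that("exact-count mixes are honored and infeasible ones rejected", {
  counts <- c(AP_FIRST_LINE = 6, IN_NO_MET_WITHIN_6MO = 4)
  g <- generate_cohort(generator_config(n_patients_per_sector = 5,
                                        reason_mix = counts, seed = 9))
  res <- audit_cohort(g$cohort, load_catalog())
  expect_equal(sum(res$reason == "AP_FIRST_LINE"), 6)
  expect_equal(sum(res$reason == "IN_NO_MET_WITHIN_6MO"), 4)

  expect_error(
    generator_config(n_patients_per_sector = 2,
                     reason_mix = c(AP_FIRST_LINE = 7)),
    "infeasible"
  )
})

test_that("an empty generated cohort is a valid header-only cohort", {
  g <- generate_cohort(generator_config(n_patients_per_sector = 0, seed = 1))
  expect_equal(nrow(g$cohort), 0)
  expect_equal(nrow(g$history), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g$cohort, path)
  expect_equal(nrow(read_cohort(path)), 0)
})

test_that("generated histories respect the structural constraints", {
  g <- generate_cohort(generator_config(n_patients_per_sector = 50, seed = 77))
  hm <- history_metrics(
    g$history,
    index_claims = setNames(g$cohort$hospital_id, g$cohort$patient_id),
    sector_map = setNames(g$cohort$sector, g$cohort$patient_id)
  )
  expect_true(all(hm$patients$n_claims >= 1))
  expect_true(all(hm$patients$n_hospitals <= 3))
  expect_true(all(hm$patients$share_index >= 0 & hm$patients$share_index <= 1))
  # every patient's index claim is in the history at the index hospital
  expect_true(all(g$cohort$claim_id %in% g$history$claim_id))
})
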