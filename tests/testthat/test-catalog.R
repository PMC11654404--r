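test_that("catalog lookups are case- and whitespace-insensitive", {
  cat <- make_test_catalog(list(
    Tamoxifen = list("non_chemotherapy"),
    `Adriamycin+Cyclophosphamide` = list("adjuvant_regimen")
  ))
  hormonal <- classify_regimen("tamoxifen", cat)
  expect_equal(hormonal$roles, "non_chemotherapy")
  expect_true(hormonal$pure_non_chemotherapy)

  combo <- classify_regimen("adriamycin + cyclophosphamide", cat)
  expect_equal(combo$roles, "adjuvant_regimen")
  # the same combination supplied as a drug list matches the whole-regimen key
  combo2 <- classify_regimen(c("Cyclophosphamide", "ADRIAMYCIN"), cat)
  expect_equal(combo2$roles, "adjuvant_regimen")
})

test_that("empty catalogs classify nothing and bad roles are rejected", {
  empty <- make_test_catalog(list())
  res <- classify_regimen(c("paclitaxel"), empty)
  expect_length(res$roles, 0)
  expect_equal(res$unclassified_drugs, "paclitaxel")
  expect_false(res$pure_non_chemotherapy)

  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(drugs = list(foo = list("third_line"))), path)
  expect_error(load_catalog(path), "foo.*third_line")
})

test_that("roles union over matched drugs; unknowns are reported not raised", {
  cat <- make_test_catalog(list(aaa = list("first_line_palliative")))
  res <- classify_regimen(c("aaa", "mystery"), cat)
  expect_equal(res$roles, "first_line_palliative")
  expect_equal(res$unclassified_drugs, "mystery")
})

test_that("classification is order-invariant and monotone in the catalog", {
  cat <- make_test_catalog(list(
    aaa = list("first_line_palliative"),
    bbb = list("second_line_palliative", "adjuvant_regimen"),
    ccc = list("non_chemotherapy")
  ))
  bigger <- make_test_catalog(list(
    aaa = list("first_line_palliative"),
    bbb = list("second_line_palliative", "adjuvant_regimen"),
    ccc = list("non_chemotherapy"),
    ddd = list("adjuvant_regimen"),
    `aaa+ccc` = list("adjuvant_regimen")
  ))
  set.seed(4242)
  pool <- c("aaa", "bbb", "ccc", "ddd", "eee")
  for (i in 1:50) {
    drugs <- sample(pool, sample(1:4, 1))
    base <- classify_regimen(drugs, cat)
    perm <- classify_regimen(sample(drugs), cat)
    expect_equal(sort(base$roles), sort(perm$roles))
    grown <- classify_regimen(drugs, bigger)
    expect_true(all(base$roles %in% grown$roles))
  }
})

test_that("lookup agrees with a naive dictionary-scan oracle", {
  set.seed(99)
  names_pool <- c("d1", "d2", "d3", "d4", "d5", "d6", "d1+d2", "d3+d4",
                  "d2+d5", "d5+d6")
  roles_pool <- c("first_line_palliative", "second_line_palliative",
                  "non_chemotherapy", "adjuvant_regimen")
  entries <- setNames(
    lapply(seq_along(names_pool),
           function(i) as.list(sample(roles_pool, sample(1:2, 1)))),
    names_pool
  )
  cat <- make_test_catalog(entries)

  naive_lookup <- function(drugs) {
    roles <- character()
    for (d in drugs) {
      for (nm in names(entries)) {
        if (tolower(gsub(" ", "", d)) == tolower(gsub(" ", "", nm))) {
          roles <- c(roles, unlist(entries[[nm]]))
        }
      }
    }
    if (length(drugs) > 1) {
      for (joined in c(paste(tolower(drugs), collapse = "+"),
                       paste(sort(tolower(drugs)), collapse = "+"))) {
        for (nm in names(entries)) {
          if (joined == tolower(nm)) roles <- c(roles, unlist(entries[[nm]]))
        }
      }
    }
    sort(unique(roles))
  }
  for (i in 1:200) {
    drugs <- sample(c("d1", "d2", "d3", "d4", "d5", "d6", "zz"),
                    sample(1:3, 1))
    expect_equal(classify_regimen(drugs, cat)$roles, naive_lookup(drugs),
                 info = paste(drugs, collapse = ";"))
  }
})
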