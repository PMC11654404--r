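# Shared test fixtures: catalogs are written as YAML temp files and loaded
# through the public API so the config path is exercised everywhere.

make_test_catalog <- function(entries, source = "test catalog") {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(list(source = source, drugs = entries), path)
  load_catalog(path)
}

# Four-role micro catalog used by the engine truth-table tests.
micro_catalog <- function() {
  make_test_catalog(list(
    aaa = list("first_line_palliative"),
    bbb = list("second_line_palliative"),
    ccc = list("non_chemotherapy"),
    ddd = list("adjuvant_regimen")
  ), source = "micro test catalog")
}

# Drug lists realizing each regimen-role profile under micro_catalog().
profile_drugs <- function(profile) {
  switch(profile,
    first = "aaa",
    second = "bbb",
    nonchemo = "ccc",
    adjuvant = "ddd",
    unclassified = "zzz",
    first_and_second = c("aaa", "bbb"),
    stop("unknown profile ", profile)
  )
}
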