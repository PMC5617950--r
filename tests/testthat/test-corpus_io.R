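test_that("load_corpus reads a manifest plus text files and counts cohorts", {
  corp <- load_corpus(test_path("fixtures", "manifest.csv"),
                      test_path("fixtures"))
  expect_s3_class(corp, "report_corpus")
  expect_equal(nrow(corp$reports), 3L)
  expect_equal(corp$n_mut, 2L)
  expect_equal(corp$n_wt, 1L)
  expect_match(corp$reports$text[1], "^Innumerable")
})

test_that("load_corpus sniffs tab-delimited manifests", {
  dir <- withr::local_tempdir()
  writeLines(c("report_id\tpatient_id\tcohort",
               "a\tp1\tMUTANT", "b\tp2\tWILDTYPE"),
             file.path(dir, "man.tsv"))
  writeLines("some mutant report text here", file.path(dir, "a.txt"))
  writeLines("some wildtype report text here", file.path(dir, "b.txt"))
  corp <- load_corpus(file.path(dir, "man.tsv"), dir)
  expect_equal(corp$n_mut, 1L)
  expect_equal(corp$n_wt, 1L)
})

test_that("manifest violations are hard errors naming the offender", {
  dir <- withr::local_tempdir()
  writeLines("text", file.path(dir, "a.txt"))
  writeLines("text", file.path(dir, "b.txt"))

  writeLines(c("report_id,patient_id,cohort", "a,p1,KRAS2"),
             file.path(dir, "bad_cohort.csv"))
  expect_error(load_corpus(file.path(dir, "bad_cohort.csv"), dir),
               "unknown cohort label.*KRAS2")

  writeLines(c("report_id,patient_id,cohort", "a,p1,MUTANT", "a,p1,MUTANT"),
             file.path(dir, "dup.csv"))
  expect_error(load_corpus(file.path(dir, "dup.csv"), dir),
               "duplicate report_id.*a")

  writeLines(c("report_id,patient_id,cohort", "missing,p1,MUTANT"),
             file.path(dir, "gone.csv"))
  expect_error(load_corpus(file.path(dir, "gone.csv"), dir),
               "report file not found.*missing")

  # one patient in both cohorts violates the corpus invariant
  writeLines(c("report_id,patient_id,cohort", "a,p1,MUTANT", "b,p1,WILDTYPE"),
             file.path(dir, "mixed.csv"))
  expect_error(load_corpus(file.path(dir, "mixed.csv"), dir),
               "both cohorts.*p1")
})

test_that("write_corpus then load_corpus round-trips exactly", {
  corp <- make_corpus(
    c("Report one with enough text to stand alone.",
      "Second report, byte-exact round trip expected é."),
    c("MUTANT", "WILDTYPE"))
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- load_corpus(file.path(dir, "manifest.csv"), dir)
  expect_equal(back$reports, corp$reports)
  expect_equal(back$n_mut, corp$n_mut)
  expect_equal(back$n_wt, corp$n_wt)
})

test_that("filter_reports drops matching and short reports, with a per-rule log", {
  texts <- c(sprintf("Clinically meaningful radiology report number %d with findings.", 1:7),
             "STATEMENT OF CHARGES — billing code 1234, see billing office.",
             "Billing document for account settlement purposes only.",
             "An appointment scheduling note for next week visit.")
  corp <- make_corpus(texts, rep(c("MUTANT", "WILDTYPE"), c(5, 5)))
  out <- filter_reports(corp, exclusion_rules(), quiet = TRUE)
  expect_equal(nrow(out$reports), 7L)
  log <- attr(out, "exclusion_log")
  expect_equal(log$n_excluded[log$rule == "billing"], 2L)
  expect_equal(log$n_excluded[log$rule == "scheduling"], 1L)

  # independent linear recount of the exclusion decision
  manual <- vapply(texts, function(tx) {
    any(vapply(c("billing", "charges", "scheduling"),
               function(p) grepl(p, tolower(tx), fixed = TRUE), logical(1))) ||
      nchar(tx) < 50
  }, logical(1))
  expect_equal(nrow(out$reports), sum(!manual))
})

test_that("filtering with empty rules is the identity, and filtering is idempotent", {
  corp <- make_corpus(c("short", "a much longer report with real content in it"),
                      c("MUTANT", "WILDTYPE"))
  none <- exclusion_rules(patterns = character(0), min_chars = 0L)
  expect_equal(filter_reports(corp, none, quiet = TRUE)$reports, corp$reports)

  rules <- exclusion_rules(min_chars = 10L)
  once <- filter_reports(corp, rules, quiet = TRUE)
  twice <- filter_reports(once, rules, quiet = TRUE)
  expect_equal(twice$reports, once$reports)
  # output is a subset of input
  expect_true(all(once$reports$report_id %in% corp$reports$report_id))
})
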