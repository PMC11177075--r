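test_that("parsing turns missing codes and unmapped codes into NA, preserving rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,age,cause,witnessed,no_flow_time,first_rhythm,pad_performed,prehospital_rosc,resuscitation_attempted,region,year,cpc",
    "a,65,internal,TRUE,3,vf,FALSE,FALSE,TRUE,other,2008,5",
    "b,,internal,TRUE,0,vf,FALSE,FALSE,TRUE,other,2008,2",
    "c,70,internal,FALSE,,zz,FALSE,FALSE,TRUE,other,2008,1"
  ), f)
  d <- abc_dialect(values = list(first_rhythm = c(vf = "VF", vt = "VT")))
  rec <- read_registry(f, d)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$age, c(65L, NA, 70L))
  expect_equal(rec$first_rhythm, c("VF", "VF", NA))
})

test_that("parsing errors name a missing column and reject duplicate ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,age", "a,65"), f)
  expect_error(read_registry(f), "cause")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(dplyr::bind_rows(make_record("dup"), make_record("dup")), f2)
  expect_error(read_registry(f2), "duplicate record_id")
})

test_that("write then read is the identity, field by field", {
  cohort <- dplyr::select(synthetic_cohort_example(12, seed = 3),
                          -"intended_fate")
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(cohort, f)
  back <- read_registry(f)
  for (col in names(cohort)) {
    expect_equal(back[[col]], cohort[[col]], label = col)
  }
  # empty input yields a parseable header-only file
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_registry(cohort[0, ], f0)
  expect_equal(nrow(read_registry(f0)), 0)
})

test_that("a TSV dialect with renamed columns and recoded enums round-trips", {
  d <- abc_dialect(
    delim = "\t", missing_codes = c(".", ""),
    columns = c(record_id = "ID", cpc = "CPC_1M"),
    values = list(region = c(K = "kanto", O = "other")),
    true_codes = "Y", false_codes = "N"
  )
  cohort <- dplyr::select(synthetic_cohort_example(8, seed = 9),
                          -"intended_fate")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_registry(cohort, f, d)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_true("\"ID\"" %in% header && "\"CPC_1M\"" %in% header)
  expect_equal(as.data.frame(read_registry(f, d)), as.data.frame(cohort))
})

test_that("guideline groups partition the years, nine of them analysable", {
  expect_equal(as.character(assign_guideline_group(2008)), "G2005")
  expect_equal(as.character(assign_guideline_group(2010)), "transition_excluded")
  expect_equal(as.character(assign_guideline_group(2019)), "G2015")
  g <- assign_guideline_group(1990:2035)
  expect_false(anyNA(g))
  expect_equal(sum(g != "transition_excluded"), 9)
  expect_equal(unname(table(g)[c("G2005", "G2010", "G2015")]),
               array(c(3L, 3L, 3L)), ignore_attr = TRUE)
})

test_that("each selection filter catches its own violation, first failure wins", {
  records <- dplyr::bind_rows(
    make_record("clean", cpc = 2L),
    make_record("young", age = 17L),
    make_record("trauma", cause = "external_trauma"),
    make_record("noscore", witnessed = NA, no_flow_time = NA),
    make_record("nocpc", cpc = NA),
    make_record("rosc", prehospital_rosc = TRUE),
    make_record("kanto", region = "kanto"),
    make_record("transition", year = 2011L)
  )
  cohort <- apply_selection_filters(records)
  log <- exclusion_log(cohort)
  expect_equal(nrow(cohort), 1)
  expect_equal(cohort$record_id, "clean")
  expect_equal(log$n_excluded, rep(1L, 7))
  expect_equal(attr(log, "n_input") - sum(log$n_excluded),
               attr(log, "n_retained"))

  # a record failing several criteria is tallied once, at the first
  multi <- apply_selection_filters(
    make_record("m", age = 15L, cause = "external_trauma", region = "kanto"))
  tl <- exclusion_log(multi)$n_excluded
  expect_equal(sum(tl), 1)
  expect_equal(tl[1], 1L)
})

test_that("PAD with missing rhythm is scoreable, missing witnessed is not", {
  ok <- make_record("padonly", first_rhythm = NA, pad_performed = TRUE)
  expect_equal(nrow(apply_selection_filters(ok)), 1)
  bad <- make_record("nowit", witnessed = NA, pad_performed = TRUE)
  log <- exclusion_log(apply_selection_filters(bad))
  expect_equal(log$n_excluded[log$step == "score_not_computable"], 1L)
})

test_that("filtering is row-order invariant and accounts for every record", {
  cohort <- synthetic_cohort_example(400, seed = 11)
  log1 <- exclusion_log(apply_selection_filters(cohort))
  perm <- cohort[sample(nrow(cohort)), ]
  filtered <- apply_selection_filters(perm)
  log2 <- exclusion_log(filtered)
  expect_equal(log2$n_excluded, log1$n_excluded)
  expect_equal(sort(filtered$record_id),
               sort(apply_selection_filters(cohort)$record_id))
  expect_equal(attr(log2, "n_input") - sum(log2$n_excluded),
               attr(log2, "n_retained"))

  empty <- apply_selection_filters(cohort[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(exclusion_log(empty)$n_excluded, rep(0L, 7))
})

test_that("write, reload and refilter reproduces the exclusion log", {
  cohort <- dplyr::select(synthetic_cohort_example(500, seed = 21),
                          -"intended_fate")
  log1 <- exclusion_log(apply_selection_filters(cohort))
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(cohort, f)
  log2 <- exclusion_log(apply_selection_filters(read_registry(f)))
  expect_equal(log2$n_excluded, log1$n_excluded)
})
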