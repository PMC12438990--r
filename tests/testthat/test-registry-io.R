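make_raw <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(person_id = r[[1]], sex = r[[2]], birth_date = r[[3]],
                   event_date = r[[4]], event_type = r[[5]], icd10 = r[[6]],
                   parental_education = r[[7]])
  }))
}

test_that("valid rows pass and rejected rows carry reasons", {
  raw <- make_raw(
    list("p1", "F", "2000-01-01", "2010-05-01", "DIAGNOSIS", "F32.1", "SHORT"),
    list("p1", "F", "2000-01-01", "2011-05-01", "DIAGNOSIS", "F43", "SHORT"),
    list("p2", "M", "2001-02-03", "2012-01-01", "DIAGNOSIS", "F84.0", "LONG"),
    list("p3", "M", "2005-01-01", "2004-12-31", "DIAGNOSIS", "F90", "LONG"),
    list("p4", "F", "2000-01-01", "2010-01-01", "DIAGNOSIS", "G40.1", "SHORT"),
    list("p5", "F", "2000-01-01", "2010-01-01", "DIAGNOSIS", "notacode", "SHORT"),
    list("p6", "X", "2000-01-01", "2010-01-01", "DIAGNOSIS", "F32", "SHORT"),
    list("p7", "F", "2000-01-01", "2010-99-01", "DIAGNOSIS", "F32", "SHORT"),
    list("p8", "F", "2000-01-01", "2010-01-01", "DEATH", "F32", "SHORT")
  )
  got <- validate_records(raw)
  expect_equal(got$report$n_total, 9)
  expect_equal(got$report$n_accepted, 3)
  expect_equal(got$report$n_accepted + got$report$n_rejected,
               got$report$n_total)
  reasons <- setNames(got$report$rejects$reason, got$report$rejects$person_id)
  expect_equal(unname(reasons[c("p3", "p4", "p5", "p6", "p7", "p8")]),
               c("date_order", "non_F_code", "bad_code", "bad_sex",
                 "bad_date", "code_on_nondiagnosis"))
})

test_that("death consistency: one death per person, nothing after it", {
  raw <- make_raw(
    list("p1", "F", "2000-01-01", "2010-01-01", "DIAGNOSIS", "F32", "SHORT"),
    list("p1", "F", "2000-01-01", "2012-01-01", "DEATH", "", "SHORT"),
    list("p1", "F", "2000-01-01", "2013-01-01", "DIAGNOSIS", "F43", "SHORT"),
    list("p1", "F", "2000-01-01", "2014-01-01", "DEATH", "", "SHORT")
  )
  got <- validate_records(raw)
  expect_equal(got$report$n_accepted, 2)
  expect_setequal(got$report$rejects$reason,
                  c("after_death", "duplicate_death"))
})

test_that("records round-trip through the event file format", {
  raw <- make_raw(
    list("p1", "F", "2000-01-01", "2010-05-01", "DIAGNOSIS", "F32.1", "SHORT"),
    list("p2", "M", "2001-02-03", "2012-01-01", "DIAGNOSIS", "F84.0", "LONG"),
    list("p2", "M", "2001-02-03", "2013-06-01", "EMIGRATION", "", "LONG")
  )
  rec <- validate_records(raw)$records
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, tmp)
  back <- read_records(tmp)
  expect_equal(back$records, rec)
  expect_equal(back$report$n_rejected, 0)
  # tab-delimited input is accepted too
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  tab <- readLines(tmp)
  writeLines(gsub(",", "\t", tab), tmp2)
  expect_equal(read_records(tmp2)$records, rec)
})

test_that("a missing column is a schema error", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,sex,birth_date", "p1,F,2000-01-01"), tmp)
  expect_error(read_records(tmp), "missing column")
})

test_that("D1 is the first under-18 diagnosis; same-day ties keep the last row", {
  rec <- dplyr::bind_rows(
    # first at age 9, later at 14 -> D1 is the age-9 record
    person_records("a", "2009-01-10", "F84.0"),
    rec_row("a", "2014-03-01", "DIAGNOSIS", "F90"),
    # only diagnosis at age 18.2 -> excluded
    rec_row("b", "2018-03-15", "DIAGNOSIS", "F32"),
    # two diagnoses the same day: file order F32.1 then F43.2 -> D1 = F43.2
    rec_row("c", "2010-06-01", "DIAGNOSIS", "F32.1"),
    rec_row("c", "2010-06-01", "DIAGNOSIS", "F43.2")
  )
  idx <- identify_d1(rec, TAX)
  expect_setequal(idx$d1$person_id, c("a", "c"))
  expect_equal(idx$d1$d1_code[idx$d1$person_id == "a"], "F84.0")
  expect_equal(idx$d1$d1_category[idx$d1$person_id == "a"], "ASD")
  expect_equal(idx$d1$d1_code[idx$d1$person_id == "c"], "F43.2")
  expect_equal(idx$excluded$person_id, "b")
  expect_equal(idx$excluded$reason, "no_under18_diagnosis")
  expect_equal(idx$d1$age_band[idx$d1$person_id == "a"], "0-10")
  expect_equal(idx$d1$age_band[idx$d1$person_id == "c"], "0-10")
})

test_that("unmappable diagnoses cannot anchor a D1", {
  rec <- dplyr::bind_rows(
    rec_row("u", "2008-01-01", "DIAGNOSIS", "F07.0"),
    rec_row("u", "2009-01-01", "DIAGNOSIS", "F84.1")
  )
  idx <- identify_d1(rec, TAX)
  expect_equal(idx$d1$d1_code, "F84.1")
})
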