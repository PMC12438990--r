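test_that("a lone D1 projects to a constant 10-state sequence", {
  rec <- person_records("p1", "2005-03-10", "F32.1")
  seqs <- build_sequences(rec, TAX)
  expect_equal(nrow(seqs), 1)
  expect_equal(seq_states(seqs), rep("SRD", 10))
  expect_length(seq_states(seqs), 10)
})

test_that("hand-traced windowing: shift at month 30, death at month 54", {
  rec <- person_records(
    "p1", "2005-03-10", "F32.1",
    list(month = 30, code = "F60"),            # period 3
    list(month = 54, type = "DEATH")           # period 5
  )
  seqs <- build_sequences(rec, TAX)
  expect_equal(seq_states(seqs),
               c("SRD", "SRD", "PD", "PD", rep("DEAD", 6)))
})

test_that("the last diagnosis within a window wins", {
  rec <- person_records(
    "p1", "2005-03-10", "F84.0",
    list(month = 38, code = "F90"),   # period 4, earlier
    list(month = 44, code = "F84.1")  # period 4, later
  )
  seqs <- build_sequences(rec, TAX)
  expect_equal(seq_states(seqs)[4], "ASD")
  # same-day tie inside a window: last file row wins
  rec2 <- dplyr::bind_rows(
    person_records("p2", "2005-03-10", "F84.0"),
    rec_row("p2", "2006-06-01", "DIAGNOSIS", "F90"),
    rec_row("p2", "2006-06-01", "DIAGNOSIS", "F43")
  )
  expect_equal(seq_states(build_sequences(rec2, TAX))[2], "SAD")
})

test_that("death overrides a diagnosis in the same window and absorbs", {
  rec <- person_records(
    "p1", "2005-03-10", "F32",
    list(month = 25, code = "F43"),
    list(month = 27, type = "DEATH")  # same window (period 3) as the F43
  )
  st <- seq_states(build_sequences(rec, TAX))
  expect_equal(st[3:10], rep("DEAD", 8))
  # emigration absorbs the same way
  rec2 <- person_records("p2", "2005-03-10", "F32",
                         list(month = 60, type = "EMIGRATION"))
  st2 <- seq_states(build_sequences(rec2, TAX))
  expect_equal(st2, c(rep("SRD", 5), rep("EMIGRATED", 5)))
})

test_that("unmapped diagnoses are ignored in windowing and counted", {
  rec <- person_records("p1", "2005-03-10", "F32",
                        list(month = 14, code = "F07.0"))
  seqs <- build_sequences(rec, TAX)
  expect_equal(seq_states(seqs), rep("SRD", 10))
  expect_equal(attr(seqs, "n_unmapped"), 1L)
})

test_that("sequence order is independent of input row order", {
  rec <- person_records(
    "p1", "2005-03-10", "F32",
    list(month = 18, code = "F43"),
    list(month = 40, code = "F60"),
    list(month = 80, code = "F90")
  )
  shuffled <- rec[c(3, 1, 4, 2), ]
  expect_equal(seq_states(build_sequences(rec, TAX)),
               seq_states(build_sequences(shuffled, TAX)))
})

test_that("stratification partitions populated cells only", {
  rec <- dplyr::bind_rows(
    person_records("g1", "2005-01-01", "F32", sex = "F"),
    person_records("g2", "2005-01-01", "F43", sex = "F"),
    person_records("b1", "2005-01-01", "F32", sex = "M"),
    person_records("b2", "2005-01-01", "F43", sex = "M")
  )
  seqs <- build_sequences(rec, TAX)
  sets <- build_sequence_set(seqs)
  expect_length(sets, 4)
  expect_setequal(names(sets), c("SRD/F", "SRD/M", "SAD/F", "SAD/M"))
  expect_equal(sum(vapply(sets, nrow, integer(1))), nrow(seqs))
  expect_error(build_sequence_set(seqs, by = "nope"), "unknown stratifier")
})

test_that("frequency table suppresses sequences below the threshold", {
  mk <- function(n, id0, code) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      person_records(paste0(id0, i), "2005-01-01", code)
    }))
  }
  # counts {6, 5, 4, 3}: two displayed rows, residual 7
  rec <- dplyr::bind_rows(
    mk(6, "a", "F32"), mk(5, "b", "F43"), mk(4, "c", "F84.0"), mk(3, "d", "F90")
  )
  seqs <- build_sequences(rec, TAX)
  ft <- sequence_frequency_table(seqs, min_count = 5)
  shown <- ft[!ft$suppressed, ]
  expect_equal(shown$count, c(6L, 5L))
  expect_equal(ft$count[ft$suppressed], 7L)
  expect_equal(attr(ft, "n_suppressed_sequences"), 2L)
  expect_equal(sum(ft$count), nrow(seqs))  # suppression preserves totals
  # all identical -> a single unsuppressed row
  ft1 <- sequence_frequency_table(build_sequences(mk(7, "z", "F50"), TAX))
  expect_equal(nrow(ft1), 1)
  expect_false(ft1$suppressed)
  # below threshold entirely -> only the residual row
  ft0 <- sequence_frequency_table(build_sequences(mk(4, "y", "F50"), TAX),
                                  min_count = 5)
  expect_equal(sum(!ft0$suppressed), 0)
  expect_equal(ft0$count[ft0$suppressed], 4L)
  expect_error(sequence_frequency_table(seqs, min_count = 0), "min_count")
})

test_that("absorbing states are never left in generated cohorts", {
  cc <- cohort_config(300, p_death = 0.02, p_emigrate = 0.03, seed = 11)
  sim <- generate_cohort(cc, TAX)
  seqs <- build_sequences(sim$records, TAX)
  m <- as.matrix(as.data.frame(seqs)[paste0("s", 1:10)])
  for (ab in c("DEAD", "EMIGRATED")) {
    hit <- m == ab
    first <- apply(hit, 1, function(x) if (any(x)) which(x)[1] else NA)
    for (i in which(!is.na(first))) {
      expect_true(all(m[i, first[i]:10] == m[i, first[i]]))
    }
  }
  expect_false(any(m[, 1] %in% c("DEAD", "EMIGRATED")))
})
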