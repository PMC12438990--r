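RECORD_COLS <- c("person_id", "sex", "birth_date", "event_date",
                 "event_type", "icd10", "parental_education")

EDU_LEVELS <- c("SHORT", "MEDIUM", "LONG", "UNKNOWN")

#' Read registry-style diagnostic event records
#'
#' Reads a delimited event file (comma by default, tab accepted) with header
#' `person_id,sex,birth_date,event_date,event_type,icd10,parental_education`
#' and ISO-8601 dates. Rows violating the record contract are not dropped
#' silently: they are collected in an ingest report with a machine-readable
#' reason, and accepted + rejected always accounts for every input row.
#'
#' Validation rules, with the reason recorded on rejection:
#' * unparseable birth/event date — `bad_date`
#' * sex not `F`/`M` — `bad_sex`
#' * unknown event type — `bad_event_type`
#' * event before birth — `date_order`
#' * `DIAGNOSIS` without a code — `missing_code`
#' * syntactically invalid code — `bad_code`; valid shape but outside the
#'   mental-disorder chapter (e.g. `G40.1`) — `non_F_code`
#' * code attached to a death/emigration row — `code_on_nondiagnosis`
#' * more than one death per person — `duplicate_death`; any event dated
#'   after a person's death — `after_death`
#'
#' @param path Path to the event file.
#' @param delim Field delimiter; `NULL` (default) tries comma then tab.
#' @return A list with `records` (tibble of accepted rows, dates parsed) and
#'   `report` (an `ingest_report`).
#' @export
read_records <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           na = character())
  missing <- setdiff(RECORD_COLS, names(raw))
  if (length(missing) > 0) {
    stop("event file is missing column(s): ", paste(missing, collapse = ", "))
  }
  validate_records(raw[RECORD_COLS], source = path)
}

#' @rdname read_records
#' @param records A character-typed tibble with the record columns (as read
#'   from file, or assembled in memory).
#' @param source Label used in the report.
#' @export
validate_records <- function(records, source = "<memory>") {
  n <- nrow(records)
  rec <- tibble::as_tibble(records)
  rec$.row <- seq_len(n)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }

  birth <- suppressWarnings(lubridate::ymd(rec$birth_date))
  event <- suppressWarnings(lubridate::ymd(rec$event_date))
  flag(is.na(birth) | is.na(event), "bad_date")
  flag(!rec$sex %in% c("F", "M"), "bad_sex")
  flag(!rec$event_type %in% c("DIAGNOSIS", "DEATH", "EMIGRATION"),
       "bad_event_type")
  flag(!is.na(birth) & !is.na(event) & event < birth, "date_order")

  code <- icd10_normalize(rec$icd10)
  is_diag <- rec$event_type == "DIAGNOSIS"
  flag(is_diag & code == "", "missing_code")
  shaped <- grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", code)
  flag(is_diag & code != "" & shaped & !startsWith(code, "F"), "non_F_code")
  flag(is_diag & code != "" & !shaped, "bad_code")
  flag(!is_diag & code != "", "code_on_nondiagnosis")

  # death consistency, assessed on rows still standing
  ok <- is.na(reason)
  if (any(ok)) {
    live <- tibble::tibble(.row = rec$.row[ok], person_id = rec$person_id[ok],
                           event = event[ok], type = rec$event_type[ok])
    live <- live[order(live$person_id, live$event, live$.row), ]
    by_person <- split(seq_len(nrow(live)), live$person_id)
    for (idx in by_person) {
      deaths <- idx[live$type[idx] == "DEATH"]
      if (length(deaths) == 0) next
      reason[live$.row[deaths[-1]]] <- "duplicate_death"
      d_date <- live$event[deaths[[1]]]
      late <- idx[live$event[idx] > d_date]
      reason[live$.row[setdiff(late, deaths)]] <- "after_death"
    }
  }

  keep <- is.na(reason)
  accepted <- tibble::tibble(
    person_id = rec$person_id[keep],
    sex = rec$sex[keep],
    birth_date = birth[keep],
    event_date = event[keep],
    event_type = rec$event_type[keep],
    icd10 = code[keep],
    parental_education = ifelse(rec$parental_education[keep] %in% EDU_LEVELS,
                                rec$parental_education[keep], "UNKNOWN")
  )
  report <- structure(
    list(
      source = source,
      n_total = n,
      n_accepted = sum(keep),
      n_rejected = sum(!keep),
      rejects = tibble::tibble(row = rec$.row[!keep],
                               person_id = rec$person_id[!keep],
                               reason = reason[!keep])
    ),
    class = "ingest_report"
  )
  list(records = accepted, report = report)
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("<ingest_report> ", x$source, "\n",
      "  rows: ", x$n_total, "  accepted: ", x$n_accepted,
      "  rejected: ", x$n_rejected, "\n", sep = "")
  if (x$n_rejected > 0) {
    tab <- table(x$rejects$reason)
    for (r in names(tab)) cat("   - ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Write records / ingest reports
#'
#' `write_records()` writes the canonical comma-delimited event file with
#' ISO-8601 dates; reading it back with [read_records()] reproduces the
#' records exactly. `write_ingest_report()` writes the report as JSON.
#'
#' @param records Tibble of accepted records.
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  out <- records[RECORD_COLS]
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$event_date <- format(out$event_date, "%Y-%m-%d")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_records
#' @param report An `ingest_report`.
#' @export
write_ingest_report <- function(report, path) {
  jsonlite::write_json(
    list(source = report$source, n_total = report$n_total,
         n_accepted = report$n_accepted, n_rejected = report$n_rejected,
         rejects = report$rejects),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Identify each person's first-time main diagnosis (D1)
#'
#' The D1 is the chronologically first diagnosis received strictly before age
#' 18.0 years (decimal age computed as days since birth / 365.25). Multiple
#' diagnoses on the same day are resolved by keeping the last one in file
#' order, mirroring the last-diagnosis-per-window convention used for the
#' sequences. Persons with no qualifying diagnosis (only adult-age
#' diagnoses, unmappable codes, or death before any diagnosis) are excluded
#' and reported.
#'
#' Note: the record format carries main diagnoses only; if a source mixes
#' main and secondary diagnoses, callers must pre-filter to main diagnoses
#' before indexing.
#'
#' @param records Tibble of accepted records (see [read_records()]).
#' @param taxonomy A `diag_taxonomy`; diagnoses mapping to `UNMAPPED` are
#'   ignored when locating the D1.
#' @return A list of class `cohort_index`: `d1` (one row per indexed person:
#'   ids, D1 date/code/category, demographics, decimal age and age band at
#'   D1, entry year) and `excluded` (person ids with reasons).
#' @export
identify_d1 <- function(records, taxonomy) {
  stopifnot(inherits(taxonomy, "diag_taxonomy"))
  rec <- records
  rec$.row <- seq_len(nrow(rec))
  diag <- rec[rec$event_type == "DIAGNOSIS", ]
  diag$category <- map_code_to_category(diag$icd10, taxonomy)
  diag <- diag[diag$category != "UNMAPPED", ]
  diag$age <- as.numeric(diag$event_date - diag$birth_date) / 365.25
  under18 <- diag[diag$age < 18.0, ]
  # chronological order; same-day ties -> last row in file order wins
  under18 <- under18[order(under18$person_id, under18$event_date, -under18$.row), ]
  d1 <- under18[!duplicated(under18$person_id), ]

  all_persons <- unique(rec$person_id)
  out_ids <- setdiff(all_persons, d1$person_id)
  excluded <- tibble::tibble(person_id = out_ids,
                             reason = "no_under18_diagnosis")
  if (length(out_ids) > 0) {
    had_any <- out_ids %in% rec$person_id[rec$event_type == "DIAGNOSIS"]
    excluded$reason[!had_any] <- "no_diagnosis"
  }

  d1_tbl <- tibble::tibble(
    person_id = d1$person_id,
    sex = d1$sex,
    birth_date = d1$birth_date,
    d1_date = d1$event_date,
    d1_code = d1$icd10,
    d1_category = d1$category,
    age_at_d1 = d1$age,
    age_band = ifelse(d1$age < 11, "0-10", "11-17"),
    parental_education = d1$parental_education,
    entry_year = lubridate::year(d1$event_date)
  )
  structure(list(d1 = d1_tbl, excluded = excluded), class = "cohort_index")
}

#' @export
print.cohort_index <- function(x, ...) {
  cat("<cohort_index> ", nrow(x$d1), " indexed persons, ",
      nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}
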