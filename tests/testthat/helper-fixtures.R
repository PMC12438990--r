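# shared fixtures: in-memory record builders and a day-resolution oracle

suppressMessages(library(lubridate))

TAX <- load_taxonomy()

rec_row <- function(person_id, event_date, event_type = "DIAGNOSIS",
                    icd10 = "", sex = "F", birth_date = "2000-01-01",
                    parental_education = "MEDIUM") {
  tibble::tibble(
    person_id = person_id, sex = sex,
    birth_date = as.Date(birth_date), event_date = as.Date(event_date),
    event_type = event_type, icd10 = icd10,
    parental_education = parental_education
  )
}

# person with D1 at a given date plus later events given as offsets in months
person_records <- function(id, d1_date, d1_code, ...,
                           sex = "F", birth_date = "2000-01-01") {
  d1_date <- as.Date(d1_date)
  events <- list(...)
  rows <- list(rec_row(id, d1_date, "DIAGNOSIS", d1_code,
                       sex = sex, birth_date = birth_date))
  for (ev in events) {
    date <- d1_date %m+% months(ev$month) + (ev$day %||% 0)
    rows[[length(rows) + 1]] <- rec_row(
      id, date, ev$type %||% "DIAGNOSIS", ev$code %||% "",
      sex = sex, birth_date = birth_date
    )
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force day-resolution oracle: assign every day its prevailing state,
# then read off the state on each 12-month window's final day
oracle_sequence <- function(rec, d1_date, taxonomy = TAX, n_periods = 10) {
  rec$.row <- seq_len(nrow(rec))
  dg <- rec[rec$event_type == "DIAGNOSIS", ]
  dg$cat <- map_code_to_category(dg$icd10, taxonomy)
  dg <- dg[dg$cat != "UNMAPPED" & dg$event_date >= d1_date, ]
  dg <- dg[order(dg$event_date, dg$.row), ]
  dd <- rec$event_date[rec$event_type == "DEATH"]
  ee <- rec$event_date[rec$event_type == "EMIGRATION"]
  states <- character(n_periods)
  for (k in seq_len(n_periods)) {
    last_day <- (d1_date %m+% months(12L * k)) - 1
    d_in <- dd[dd <= last_day]
    e_in <- ee[ee <= last_day]
    if (length(d_in) > 0 && (length(e_in) == 0 || min(d_in) <= min(e_in))) {
      states[k] <- "DEAD"
    } else if (length(e_in) > 0) {
      states[k] <- "EMIGRATED"
    } else {
      upto <- dg[dg$event_date <= last_day, ]
      states[k] <- upto$cat[nrow(upto)]
    }
  }
  states
}

seq_states <- function(seqs, i = 1) {
  unname(unlist(seqs[i, grep("^s[0-9]+$", names(seqs))]))
}
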