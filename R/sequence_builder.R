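#' Build annual diagnostic state sequences
#'
#' Converts each indexed person's dated records into an ordered state
#' sequence of `n_periods` 12-month windows anchored at the D1 date. Window
#' `k` covers `[d1 + 12(k-1) months, d1 + 12k months)` (month arithmetic
#' clamps at month ends, so a Feb-29 anchor advances to Feb-28). The rules:
#'
#' * a window's state is the category of the *last* diagnosis dated inside
#'   it (same-day ties resolved by file order) — the last diagnosis in a
#'   period is taken to have the highest clinical validity;
#' * windows without a diagnosis carry the prevailing state forward
#'   (prevailing-diagnosis projection);
#' * a death or emigration inside a window sets that window and all later
#'   windows to `DEAD`/`EMIGRATED` (death wins same-window ties), overriding
#'   any diagnosis in the same window — the absorbing states are never left;
#' * diagnoses mapping to `UNMAPPED` are ignored (their count is attached as
#'   the `n_unmapped` attribute);
#' * a re-diagnosis with the prevailing category leaves the state unchanged,
#'   so within-category code changes are not shifts.
#'
#' @param records Accepted event records (see [read_records()]).
#' @param taxonomy A `diag_taxonomy`.
#' @param index Optional `cohort_index`; computed via [identify_d1()] when
#'   omitted.
#' @param n_periods Number of annual windows (default 10).
#' @return A tibble of class `diag_seqs`, one row per indexed person:
#'   `person_id`, `sex`, `d1_category`, `d1_code`, `d1_date`, `age_at_d1`,
#'   `age_band`, `parental_education`, `entry_year` and state columns
#'   `s1..s<n_periods>`. The full 21-state alphabet is attached as the
#'   `alphabet` attribute.
#' @export
build_sequences <- function(records, taxonomy, index = NULL, n_periods = 10) {
  stopifnot(inherits(taxonomy, "diag_taxonomy"), n_periods >= 1)
  if (is.null(index)) index <- identify_d1(records, taxonomy)
  d1 <- index$d1
  if (nrow(d1) == 0) stop("no indexed persons: cannot build sequences")

  rec <- records
  rec$.row <- seq_len(nrow(rec))
  rec <- rec[rec$person_id %in% d1$person_id, ]
  pos <- match(rec$person_id, d1$person_id)
  rec$d1_date <- d1$d1_date[pos]

  # period index: number of window starts at or before the event
  period <- rep(0L, nrow(rec))
  for (k in seq_len(n_periods)) {
    bound <- rec$d1_date %m+% months(12L * (k - 1L))
    period <- period + (rec$event_date >= bound)
  }
  end_bound <- rec$d1_date %m+% months(12L * n_periods)
  rec$period <- ifelse(rec$event_date >= rec$d1_date &
                         rec$event_date < end_bound, period, NA_integer_)
  rec <- rec[!is.na(rec$period), ]

  diag <- rec[rec$event_type == "DIAGNOSIS", ]
  diag$category <- map_code_to_category(diag$icd10, taxonomy)
  n_unmapped <- sum(diag$category == "UNMAPPED")
  diag <- diag[diag$category != "UNMAPPED", ]
  # last diagnosis per person-window; same-day ties -> last file row
  diag <- diag[order(diag$person_id, diag$period, diag$event_date, diag$.row), ]
  last <- diag[!duplicated(diag[c("person_id", "period")], fromLast = TRUE), ]

  np <- n_periods
  n <- nrow(d1)
  states <- matrix(NA_character_, n, np)
  i <- match(last$person_id, d1$person_id)
  states[cbind(i, last$period)] <- last$category
  # the D1 itself guarantees window 1 is populated
  for (k in seq_len(np)[-1]) {
    carry <- is.na(states[, k])
    states[carry, k] <- states[carry, k - 1]
  }

  # absorbing events: earliest death / emigration window, death wins ties
  absorb <- rec[rec$event_type %in% c("DEATH", "EMIGRATION"), ]
  if (nrow(absorb) > 0) {
    absorb <- absorb[order(absorb$person_id, absorb$period,
                           absorb$event_type != "DEATH"), ]
    first_ab <- absorb[!duplicated(absorb$person_id), ]
    ai <- match(first_ab$person_id, d1$person_id)
    for (j in seq_along(ai)) {
      lab <- if (first_ab$event_type[j] == "DEATH") "DEAD" else "EMIGRATED"
      states[ai[j], first_ab$period[j]:np] <- lab
    }
  }

  out <- d1[c("person_id", "sex", "d1_category", "d1_code", "d1_date",
              "age_at_d1", "age_band", "parental_education", "entry_year")]
  st <- tibble::as_tibble(as.data.frame(states, stringsAsFactors = FALSE))
  names(st) <- paste0("s", seq_len(np))
  out <- dplyr::bind_cols(out, st)
  structure(out, class = c("diag_seqs", class(out)),
            alphabet = state_alphabet(taxonomy), n_unmapped = n_unmapped)
}

state_cols <- function(seqs) grep("^s[0-9]+$", names(seqs), value = TRUE)

state_matrix <- function(seqs) {
  as.matrix(as.data.frame(seqs)[, state_cols(seqs), drop = FALSE])
}

#' Partition sequences into strata
#'
#' Splits a `diag_seqs` table by stratifier columns (default D1 category and
#' sex, the primary stratification; `age_band`, `parental_education` and
#' `entry_year` are also available). Empty strata cannot arise (only
#' populated combinations are returned); each element keeps the alphabet
#' attribute.
#'
#' @param seqs A `diag_seqs` tibble.
#' @param by Character vector of stratifier column names.
#' @return Named list of `diag_seqs` tibbles; names join the stratifier
#'   values with `"/"`.
#' @export
build_sequence_set <- function(seqs, by = c("d1_category", "sex")) {
  bad <- setdiff(by, names(seqs))
  if (length(bad) > 0) stop("unknown stratifier(s): ", paste(bad, collapse = ", "))
  key <- do.call(paste, c(lapply(by, function(b) seqs[[b]]), sep = "/"))
  out <- split(seqs, key)
  lapply(out, function(s) {
    structure(s, class = class(seqs), alphabet = attr(seqs, "alphabet"))
  })
}

#' Distinct-sequence frequency table with small-cell suppression
#'
#' Tabulates the distinct state sequences of a stratum in descending
#' frequency. Sequences supported by fewer than `min_count` persons are
#' never displayed individually: they are pooled into a single residual row
#' (`sequence = NA`, `suppressed = TRUE`) whose count is reported only in
#' aggregate, so displayed plus residual always equals the stratum size.
#'
#' @param seqs A `diag_seqs` tibble (typically one stratum).
#' @param min_count Minimum persons per displayed sequence (default 5).
#' @return Tibble with `sequence` (states joined by `"-"`), `count`,
#'   `suppressed`; the number of distinct suppressed sequences is attached
#'   as attribute `n_suppressed_sequences`.
#' @export
sequence_frequency_table <- function(seqs, min_count = 5) {
  if (min_count < 1) stop("min_count must be >= 1")
  if (nrow(seqs) == 0) stop("empty sequence set")
  key <- apply(state_matrix(seqs), 1, paste, collapse = "-")
  tab <- sort(table(key), decreasing = TRUE)
  shown <- tab[tab >= min_count]
  hidden <- tab[tab < min_count]
  out <- tibble::tibble(
    sequence = names(shown),
    count = as.integer(shown),
    suppressed = FALSE
  )
  if (length(hidden) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      sequence = NA_character_, count = as.integer(sum(hidden)),
      suppressed = TRUE
    ))
  }
  structure(out, n_suppressed_sequences = length(hidden))
}
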