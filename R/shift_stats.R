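#' Did a sequence ever shift diagnostic category?
#'
#' A diagnostic shift is the occurrence of any period state that is a
#' diagnostic category different from the D1 category. Re-diagnoses with
#' the D1 category are not shifts, and the absorbing states `DEAD` and
#' `EMIGRATED` never count: by default a person who dies without shifting is
#' counted as diagnostically stable (set `drop_absorbed = TRUE` to instead
#' exclude persons whose sequence enters an absorbing state without a prior
#' shift — a sensitivity option).
#'
#' @param seqs A `diag_seqs` tibble.
#' @param drop_absorbed Return `NA` for never-shifted sequences that end in
#'   an absorbing state (default `FALSE`).
#' @return Logical vector, one element per sequence.
#' @export
has_shift <- function(seqs, drop_absorbed = FALSE) {
  m <- state_matrix(seqs)
  d1 <- seqs$d1_category
  shifted <- vapply(seq_len(nrow(m)), function(i) {
    any(m[i, ] != d1[i] & !m[i, ] %in% ABSORBING_STATES)
  }, logical(1))
  if (drop_absorbed) {
    absorbed <- vapply(seq_len(nrow(m)), function(i) {
      any(m[i, ] %in% ABSORBING_STATES)
    }, logical(1))
    shifted[!shifted & absorbed] <- NA
  }
  shifted
}

#' Diagnostic-shift prevalence by stratum
#'
#' Counts and percentages of persons with at least one diagnostic shift,
#' per stratum (default D1 category by sex; use `by = "sex"` for the
#' per-sex rollup across all D1s). `stability_pct` is the complement: the
#' share whose category never changed.
#'
#' @param seqs A `diag_seqs` tibble.
#' @param by Stratifier columns.
#' @param drop_absorbed See [has_shift()].
#' @return Tibble with the stratifiers, `n`, `n_with_shift`,
#'   `pct_with_shift`, `stability_pct`.
#' @export
shift_summary <- function(seqs, by = c("d1_category", "sex"),
                          drop_absorbed = FALSE) {
  bad <- setdiff(by, names(seqs))
  if (length(bad) > 0) stop("unknown stratifier(s): ", paste(bad, collapse = ", "))
  dat <- dplyr::bind_cols(
    seqs[by], tibble::tibble(shift = has_shift(seqs, drop_absorbed))
  )
  dat |>
    dplyr::filter(!is.na(.data$shift)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_with_shift = sum(.data$shift),
      pct_with_shift = 100 * mean(.data$shift),
      stability_pct = 100 * (1 - mean(.data$shift)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
}

#' Record-level shift prevalence
#'
#' Companion to the sequence-level [shift_summary()]: a person counts as
#' shifted if *any* raw post-D1 diagnosis maps to a category other than the
#' D1 category, even if the shift is reversed within a single 12-month
#' window and therefore invisible to the windowed sequence. Reported
#' separately because the two definitions can differ.
#'
#' @param records Accepted event records.
#' @param taxonomy A `diag_taxonomy`.
#' @param by Columns of the D1 index to stratify by.
#' @return Tibble as in [shift_summary()].
#' @export
record_shift_summary <- function(records, taxonomy,
                                 by = c("d1_category", "sex")) {
  index <- identify_d1(records, taxonomy)
  d1 <- index$d1
  diag <- records[records$event_type == "DIAGNOSIS" &
                    records$person_id %in% d1$person_id, ]
  diag$category <- map_code_to_category(diag$icd10, taxonomy)
  diag <- diag[diag$category != "UNMAPPED", ]
  pos <- match(diag$person_id, d1$person_id)
  post <- diag[diag$event_date > d1$d1_date[pos], ]
  pos <- match(post$person_id, d1$person_id)
  shifted_ids <- unique(post$person_id[post$category != d1$d1_category[pos]])
  dat <- dplyr::bind_cols(
    d1[by], tibble::tibble(shift = d1$person_id %in% shifted_ids)
  )
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_with_shift = sum(.data$shift),
      pct_with_shift = 100 * mean(.data$shift),
      stability_pct = 100 * (1 - mean(.data$shift)),
      .groups = "drop"
    )
}

#' Most common subsequent-diagnosis categories for a stratum
#'
#' For each diagnostic category other than the stratum's D1 category,
#' computes the percent of the stratum's persons whose sequence ever visits
#' it (person-level counting: multiple visits count once). Absorbing states
#' are excluded. The top `k` categories by percent are returned, ties broken
#' alphabetically; categories visited by fewer than `min_count` persons are
#' flagged `suppressed` and their individual counts masked in
#' [format_top_sd()] rendering.
#'
#' @param seqs A `diag_seqs` tibble for a single D1 stratum (all rows must
#'   share `d1_category`).
#' @param k Number of categories to return (default 5).
#' @param min_count Small-cell threshold (default 5).
#' @return Tibble `category`, `n`, `pct`, `suppressed`.
#' @export
top_subsequent_categories <- function(seqs, k = 5, min_count = 5) {
  if (k < 1) stop("k must be >= 1")
  d1 <- unique(seqs$d1_category)
  if (length(d1) != 1) stop("stratum mixes D1 categories: ",
                            paste(d1, collapse = ", "))
  m <- state_matrix(seqs)
  n_persons <- nrow(m)
  visited <- lapply(seq_len(n_persons), function(i) {
    setdiff(unique(m[i, ]), c(d1, ABSORBING_STATES))
  })
  counts <- table(unlist(visited))
  if (length(counts) == 0) {
    return(tibble::tibble(category = character(0), n = integer(0),
                          pct = numeric(0), suppressed = logical(0)))
  }
  out <- tibble::tibble(
    category = names(counts),
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / n_persons
  )
  out <- out[order(-out$pct, out$category), ]
  out <- head(out, k)
  out$suppressed <- out$n < min_count
  out
}

#' @rdname top_subsequent_categories
#' @param tab Output of `top_subsequent_categories()`.
#' @export
format_top_sd <- function(tab) {
  tab$n[tab$suppressed] <- NA_integer_
  tab$pct[tab$suppressed] <- NA_real_
  tab
}
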