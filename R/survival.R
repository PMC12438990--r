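#' Bonferroni multiplicity plan
#'
#' Divides the 5% family-wise significance level by the number of tests and
#' returns the matching confidence level for interval rendering (e.g. 180
#' tests give alpha 0.05/180 ~= 0.000278 and 99.97% intervals, conventionally
#' rendered as 99.9%).
#'
#' @param n_tests Number of planned contrasts (>= 1).
#' @param alpha_family Family-wise error rate (default 0.05).
#' @return List with `n_tests`, `alpha_adjusted`, `ci_level`.
#' @examples
#' bonferroni_plan(1)    # alpha 0.05, 95% CI
#' bonferroni_plan(180)  # alpha ~0.000278
#' @export
bonferroni_plan <- function(n_tests, alpha_family = 0.05) {
  stopifnot(n_tests >= 1)
  alpha <- alpha_family / n_tests
  list(n_tests = as.integer(n_tests), alpha_adjusted = alpha,
       ci_level = 1 - alpha)
}

#' Build time-to-subsequent-diagnosis data for one contrast
#'
#' For a target D1 category and a one-cipher outcome chapter, constructs one
#' row per indexed person: exposure (target D1 vs all other D1s), follow-up
#' time in days from the D1 date, and event status. The event is the first
#' post-D1 diagnosis whose chapter equals `outcome_chapter` *and* whose
#' two-cipher block differs from the D1's own block — a repeat of the D1
#' diagnosis never qualifies, while a different two-cipher diagnosis within
#' the D1's own chapter does (set `exclude_same_chapter = TRUE` to instead
#' drop persons whose D1 lies in the outcome chapter, as a sensitivity).
#' Persons are censored at death, emigration, or `horizon_days` (default
#' 3652 days = 10 years), whichever comes first.
#'
#' @param records Accepted event records.
#' @param taxonomy A `diag_taxonomy`.
#' @param d1_category Target D1 category label.
#' @param outcome_chapter Chapter label `"F0"`..`"F9"`.
#' @param index Optional precomputed `cohort_index`.
#' @param horizon_days Administrative censoring horizon (default 3652).
#' @param exclude_same_chapter Drop persons whose D1 chapter equals the
#'   outcome chapter (default `FALSE`).
#' @return Tibble `person_id`, `sex`, `exposed` (logical), `time` (days,
#'   > 0), `event` (1 = subsequent diagnosis, 0 = censored).
#' @export
make_time_to_event <- function(records, taxonomy, d1_category,
                               outcome_chapter, index = NULL,
                               horizon_days = 3652,
                               exclude_same_chapter = FALSE) {
  stopifnot(grepl("^F[0-9]$", outcome_chapter))
  if (is.null(index)) index <- identify_d1(records, taxonomy)
  d1 <- index$d1
  if (exclude_same_chapter) {
    d1 <- d1[map_code_to_chapter(d1$d1_code) != outcome_chapter, ]
  }
  if (nrow(d1) == 0) stop("no persons available for this contrast")

  rec <- records[records$person_id %in% d1$person_id, ]
  pos <- match(rec$person_id, d1$person_id)
  rec$t <- as.numeric(rec$event_date - d1$d1_date[pos])
  post <- rec[rec$t > 0, ]

  censor_at <- function(type) {
    ev <- post[post$event_type == type, ]
    ev <- ev[order(ev$person_id, ev$t), ]
    ev <- ev[!duplicated(ev$person_id), ]
    setNames(ev$t, ev$person_id)
  }
  death_t <- censor_at("DEATH")
  emig_t <- censor_at("EMIGRATION")

  diag <- post[post$event_type == "DIAGNOSIS", ]
  diag <- diag[is_valid_icd10(diag$icd10), ]
  dpos <- match(diag$person_id, d1$person_id)
  qual <- map_code_to_chapter(diag$icd10) == outcome_chapter &
    substr(icd10_normalize(diag$icd10), 1, 3) !=
      substr(icd10_normalize(d1$d1_code[dpos]), 1, 3)
  ev <- diag[qual, ]
  ev <- ev[order(ev$person_id, ev$t), ]
  ev <- ev[!duplicated(ev$person_id), ]
  event_t <- setNames(ev$t, ev$person_id)

  cens <- pmin(
    ifelse(is.na(death_t[d1$person_id]), Inf, death_t[d1$person_id]),
    ifelse(is.na(emig_t[d1$person_id]), Inf, emig_t[d1$person_id]),
    horizon_days
  )
  et <- ifelse(is.na(event_t[d1$person_id]), Inf, event_t[d1$person_id])
  event <- as.integer(et <= cens)
  tibble::tibble(
    person_id = d1$person_id,
    sex = d1$sex,
    exposed = d1$d1_category == d1_category,
    time = ifelse(event == 1, et, cens),
    event = event
  )
}

#' Fit one proportional-hazards contrast
#'
#' Cox proportional-hazards model with a single binary exposure term,
#' maximizing the partial likelihood with Efron tie handling
#' (via [survival::coxph()]), and a Wald confidence interval on the log
#' scale at `ci_level` (99.9% when 180 Bonferroni-corrected tests are
#' planned). Degenerate inputs — an empty arm, or zero events in an arm
#' (which makes the partial-likelihood maximum unbounded) — return a
#' flagged row with undefined estimate/CI rather than an error.
#'
#' @param rows Output of [make_time_to_event()].
#' @param ci_level Confidence level (default 0.999).
#' @param d1_category,outcome_chapter Labels copied into the result.
#' @return One-row tibble: labels, `hr`, `ci_low`, `ci_high`, `ci_level`,
#'   `n_exposed`, `n_other`, `events_exposed`, `events_other`, `flag`
#'   (`"ok"`, `"empty_arm"`, `"no_events_in_arm"`, `"no_events"`).
#' @export
fit_hazard_contrast <- function(rows, ci_level = 0.999,
                                d1_category = NA_character_,
                                outcome_chapter = NA_character_) {
  stopifnot(all(rows$time > 0))
  n_exp <- sum(rows$exposed)
  n_oth <- sum(!rows$exposed)
  e_exp <- sum(rows$event[rows$exposed])
  e_oth <- sum(rows$event[!rows$exposed])
  base <- tibble::tibble(
    d1_category = d1_category, outcome_chapter = outcome_chapter,
    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    ci_level = ci_level, n_exposed = n_exp, n_other = n_oth,
    events_exposed = e_exp, events_other = e_oth, flag = "ok"
  )
  if (n_exp == 0 || n_oth == 0) {
    base$flag <- "empty_arm"
    return(base)
  }
  if (e_exp + e_oth == 0) {
    base$flag <- "no_events"
    return(base)
  }
  if (e_exp == 0 || e_oth == 0) {
    base$flag <- "no_events_in_arm"
    return(base)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ exposed,
                         data = rows, ties = "efron")
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  z <- qnorm(1 - (1 - ci_level) / 2)
  base$hr <- exp(beta)
  base$ci_low <- exp(beta - z * se)
  base$ci_high <- exp(beta + z * se)
  base
}

#' Run the full D1-by-chapter hazard-contrast grid
#'
#' For each sex, each D1 category present in the cohort, and each one-cipher
#' outcome chapter, builds the time-to-event data and fits the D1-vs-all-
#' other-D1s contrast. The Bonferroni plan is derived from the number of
#' contrasts actually attempted (those with at least one event overall), so
#' the confidence level reflects the realized grid rather than a fixed
#' count. Contrasts with no events in both arms are reported as skipped.
#'
#' @param records Accepted event records.
#' @param taxonomy A `diag_taxonomy`.
#' @param per_sex Fit separately for girls and boys (default `TRUE`).
#' @param chapters Outcome chapters (default `F0`..`F9`).
#' @param horizon_days See [make_time_to_event()].
#' @return List of class `hazard_grid`: `contrasts` (tibble, one row per
#'   sex x D1 x chapter) and `plan` (the [bonferroni_plan()] used).
#' @export
hazard_contrast_grid <- function(records, taxonomy, per_sex = TRUE,
                                 chapters = paste0("F", 0:9),
                                 horizon_days = 3652) {
  index <- identify_d1(records, taxonomy)
  sexes <- if (per_sex) c("F", "M") else "ALL"
  cells <- list()
  for (sx in sexes) {
    d1_sub <- if (sx == "ALL") index$d1 else index$d1[index$d1$sex == sx, ]
    if (nrow(d1_sub) == 0) next
    sub_index <- structure(list(d1 = d1_sub, excluded = index$excluded),
                           class = "cohort_index")
    cats <- sort(unique(d1_sub$d1_category))
    for (ct in cats) {
      for (ch in chapters) {
        rows <- make_time_to_event(records, taxonomy, ct, ch,
                                   index = sub_index,
                                   horizon_days = horizon_days)
        cells[[length(cells) + 1L]] <- list(sex = sx, d1 = ct, chapter = ch,
                                            rows = rows)
      }
    }
  }
  attempted <- vapply(cells, function(cl) sum(cl$rows$event) > 0, logical(1))
  plan <- bonferroni_plan(max(1L, sum(attempted)))
  contrasts <- dplyr::bind_rows(lapply(cells, function(cl) {
    out <- fit_hazard_contrast(cl$rows, ci_level = plan$ci_level,
                               d1_category = cl$d1,
                               outcome_chapter = cl$chapter)
    out$sex <- cl$sex
    out
  }))
  contrasts <- contrasts[c("sex", setdiff(names(contrasts), "sex"))]
  structure(list(contrasts = contrasts, plan = plan), class = "hazard_grid")
}

#' @export
print.hazard_grid <- function(x, ...) {
  cat("<hazard_grid> ", nrow(x$contrasts), " contrasts, alpha = ",
      format(x$plan$alpha_adjusted), " (", x$plan$n_tests,
      " tests)\n", sep = "")
  invisible(x)
}
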