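#' Default first-diagnosis calibration
#'
#' Per-sex first-diagnosis (D1) category mixture and onset-age parameters
#' shipped with the package. A handful of cells are pinned to published
#' nationwide anchor values for the Danish child and adolescent psychiatric
#' population (e.g. stress/adjustment disorders as the most common girls' D1
#' near 23%, ADHD near 25% for boys, late-adolescent onset for substance use
#' and bipolar disorder); the remaining cells are field-plausible synthetic
#' values. The calibration parameterizes a simulator — it is not a set of
#' register estimates.
#'
#' @return Tibble with columns `category`, `pct_female`, `pct_male`,
#'   `onset_mean_female`, `onset_mean_male`, `onset_sd`.
#' @export
default_d1_calibration <- function() {
  path <- system.file("extdata", "d1_calibration.csv",
                      package = "diagtraj", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    category = "c", .default = "d"
  ))
}

#' Default category transition matrix
#'
#' A row-stochastic matrix over the 19 diagnostic categories with a common
#' diagonal (stay) probability and the remaining mass spread uniformly over
#' the other categories. The registers this package emulates publish no
#' transition probabilities, so this default is a testability device with a
#' realistic high-self-transition structure, not an estimate.
#'
#' @param categories Character vector of category labels.
#' @param stay Per-period probability of keeping the prevailing category.
#' @return A `length(categories)` square row-stochastic matrix.
#' @export
default_transition_matrix <- function(categories, stay = 0.93) {
  k <- length(categories)
  stopifnot(k >= 2, stay >= 0, stay <= 1)
  m <- matrix((1 - stay) / (k - 1), k, k, dimnames = list(categories, categories))
  diag(m) <- stay
  m
}

#' Configure a synthetic cohort
#'
#' Full parameterization of the generative model: cohort size, sex split,
#' per-sex D1 category mixture and onset ages, a per-period category
#' transition matrix, per-period death/emigration probabilities, a parental
#' education mixture, the calendar entry window and the random seed.
#'
#' @param n_persons Number of persons to simulate.
#' @param sex_split Proportion female (default 0.4226, the share observed in
#'   the nationwide population the simulator emulates).
#' @param calibration D1 mixture/onset table, as [default_d1_calibration()].
#' @param transition_matrix Row-stochastic matrix over the calibration's
#'   categories; one transition is applied per 12-month period.
#' @param p_death,p_emigrate Per-period absorbing-event probabilities; death
#'   is drawn first and wins ties.
#' @param education_mixture Named probability vector over
#'   `SHORT`/`MEDIUM`/`LONG` parental education.
#' @param entry_window Date vector of length 2: range from which D1 dates are
#'   drawn uniformly.
#' @param n_periods Number of 12-month follow-up periods (default 10).
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_persons,
                          sex_split = 0.4226,
                          calibration = default_d1_calibration(),
                          transition_matrix = NULL,
                          p_death = 0.0005,
                          p_emigrate = 0.002,
                          education_mixture = c(SHORT = 0.25, MEDIUM = 0.45,
                                                LONG = 0.30),
                          entry_window = as.Date(c("1996-01-01", "2011-12-31")),
                          n_periods = 10,
                          seed = 1L) {
  stopifnot(n_persons >= 1, sex_split >= 0, sex_split <= 1,
            p_death >= 0, p_death <= 1, p_emigrate >= 0, p_emigrate <= 1,
            n_periods >= 1)
  cats <- calibration$category
  if (is.null(transition_matrix)) {
    transition_matrix <- default_transition_matrix(cats)
  }
  check_simplex <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  check_simplex(calibration$pct_female / sum(calibration$pct_female), "d1 mixture (F)")
  check_simplex(calibration$pct_male / sum(calibration$pct_male), "d1 mixture (M)")
  check_simplex(education_mixture, "education_mixture")
  if (!is.matrix(transition_matrix) ||
      nrow(transition_matrix) != length(cats) ||
      ncol(transition_matrix) != length(cats) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition_matrix must be a row-stochastic ",
         length(cats), "x", length(cats), " matrix", call. = FALSE)
  }
  if (is.null(dimnames(transition_matrix))) {
    dimnames(transition_matrix) <- list(cats, cats)
  }
  structure(
    list(n_persons = as.integer(n_persons), sex_split = sex_split,
         calibration = calibration, transition_matrix = transition_matrix,
         p_death = p_death, p_emigrate = p_emigrate,
         education_mixture = education_mixture,
         entry_window = as.Date(entry_window),
         n_periods = as.integer(n_periods), seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n_persons, " periods =", x$n_periods,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Expected probability of at least one diagnostic shift
#'
#' Closed-form oracle for the simulator: with a constant per-period stay
#' probability and no absorbing events, the probability of ever leaving the
#' first category over `n_transitions` independent transitions is
#' `1 - stay^n_transitions`.
#'
#' @param stay Stay (diagonal) probability, or a named transition-matrix row
#'   together with `state` naming its own category.
#' @param n_transitions Number of transitions (default 9: periods 2..10).
#' @param state Category name, required when `stay` is a full row.
#' @return Probability in `[0, 1]`.
#' @examples
#' expected_shift_probability(0.9)  # 1 - 0.9^9
#' @export
expected_shift_probability <- function(stay, n_transitions = 9, state = NULL) {
  if (length(stay) > 1) {
    stopifnot(!is.null(state), abs(sum(stay) - 1) < 1e-9)
    stay <- unname(stay[state])
  }
  stopifnot(stay >= 0, stay <= 1, n_transitions >= 0)
  1 - stay^n_transitions
}

# vectorized categorical draw: one sample per row index in `state`
sample_next_state <- function(state, transition_matrix) {
  nxt <- integer(length(state))
  for (s in sort(unique(state))) {
    idx <- which(state == s)
    nxt[idx] <- sample.int(ncol(transition_matrix), length(idx),
                           replace = TRUE, prob = transition_matrix[s, ])
  }
  nxt
}

#' Generate a synthetic registry cohort
#'
#' Simulates one person at a time-step resolution of 12-month periods: sex,
#' parental education, D1 category and onset age are drawn from the
#' calibration; the D1 record carries a concrete ICD-10 code drawn uniformly
#' from the category's code pool. For periods 2..`n_periods`, death and
#' emigration are drawn first (death wins ties) and truncate the record
#' stream; otherwise the next category is drawn from the transition row, and
#' a dated diagnosis record is emitted only on change, placed uniformly at
#' random strictly inside the period. The latent per-period state path is
#' returned as ground truth.
#'
#' @param config A [cohort_config()].
#' @param taxonomy A `diag_taxonomy`; defaults to the shipped one.
#' @return A list with `records` (event tibble in registry format, sorted by
#'   person and date) and `truth` (class `cohort_truth`: latent state path
#'   matrix, the config, and the per-category expected shift probability).
#' @export
generate_cohort <- function(config, taxonomy = load_taxonomy()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_persons
  cal <- config$calibration
  cats <- cal$category
  k <- length(cats)
  pools <- category_code_pools(taxonomy)
  if (!all(cats %in% names(pools))) {
    stop("calibration categories absent from taxonomy: ",
         paste(setdiff(cats, names(pools)), collapse = ", "))
  }

  sex <- ifelse(runif(n) < config$sex_split, "F", "M")
  edu <- sample(names(config$education_mixture), n, replace = TRUE,
                prob = config$education_mixture)
  p_f <- cal$pct_female / sum(cal$pct_female)
  p_m <- cal$pct_male / sum(cal$pct_male)
  d1_state <- integer(n)
  d1_state[sex == "F"] <- sample.int(k, sum(sex == "F"), replace = TRUE, prob = p_f)
  d1_state[sex == "M"] <- sample.int(k, sum(sex == "M"), replace = TRUE, prob = p_m)

  mu <- ifelse(sex == "F", cal$onset_mean_female[d1_state],
               cal$onset_mean_male[d1_state])
  age <- pmin(pmax(rnorm(n, mu, cal$onset_sd[d1_state]), 0.1), 17.9)

  span <- as.integer(config$entry_window[2] - config$entry_window[1])
  d1_date <- config$entry_window[1] + floor(runif(n) * (span + 1))
  birth_date <- d1_date - round(age * 365.25)

  draw_codes <- function(state_idx) {
    vapply(state_idx, function(s) {
      pool <- pools[[cats[s]]]
      pool[[sample.int(length(pool), 1L)]]
    }, character(1))
  }

  person_id <- sprintf("P%06d", seq_len(n))
  rec_list <- list(tibble::tibble(
    person_id = person_id, sex = sex, birth_date = birth_date,
    event_date = d1_date, event_type = "DIAGNOSIS",
    icd10 = draw_codes(d1_state), parental_education = edu
  ))

  np <- config$n_periods
  paths <- matrix(NA_character_, n, np)
  paths[, 1] <- cats[d1_state]
  state <- d1_state
  status <- rep("ALIVE", n)

  for (p in seq_len(np)[-1]) {
    period_start <- d1_date %m+% months(12L * (p - 1L))
    alive <- which(status == "ALIVE")
    if (length(alive) > 0) {
      dies <- alive[runif(length(alive)) < config$p_death]
      still <- setdiff(alive, dies)
      emig <- still[runif(length(still)) < config$p_emigrate]
      moved <- setdiff(still, emig)
      for (grp in list(list(idx = dies, type = "DEATH", st = "DEAD"),
                       list(idx = emig, type = "EMIGRATION", st = "EMIGRATED"))) {
        if (length(grp$idx) == 0) next
        status[grp$idx] <- grp$st
        rec_list[[length(rec_list) + 1L]] <- tibble::tibble(
          person_id = person_id[grp$idx], sex = sex[grp$idx],
          birth_date = birth_date[grp$idx],
          event_date = period_start[grp$idx] +
            sample.int(360L, length(grp$idx), replace = TRUE),
          event_type = grp$type, icd10 = "",
          parental_education = edu[grp$idx]
        )
      }
      if (length(moved) > 0) {
        nxt <- sample_next_state(state[moved], config$transition_matrix)
        changed <- moved[nxt != state[moved]]
        state[moved] <- nxt
        if (length(changed) > 0) {
          rec_list[[length(rec_list) + 1L]] <- tibble::tibble(
            person_id = person_id[changed], sex = sex[changed],
            birth_date = birth_date[changed],
            event_date = period_start[changed] +
              sample.int(360L, length(changed), replace = TRUE),
            event_type = "DIAGNOSIS", icd10 = draw_codes(state[changed]),
            parental_education = edu[changed]
          )
        }
      }
    }
    paths[, p] <- ifelse(status == "ALIVE", cats[state],
                         ifelse(status == "DEAD", "DEAD", "EMIGRATED"))
  }

  records <- dplyr::bind_rows(rec_list)
  records <- records[order(records$person_id, records$event_date), ]
  rownames(paths) <- person_id
  colnames(paths) <- paste0("s", seq_len(np))
  truth <- structure(
    list(paths = paths,
         d1_category = setNames(cats[d1_state], person_id),
         config = config,
         expected_shift = setNames(
           vapply(seq_len(k), function(s) expected_shift_probability(
             config$transition_matrix[s, s], np - 1L), numeric(1)),
           cats)),
    class = "cohort_truth"
  )
  list(records = tibble::as_tibble(records), truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("<cohort_truth> ", nrow(x$paths), " latent paths over ",
      ncol(x$paths), " periods\n", sep = "")
  invisible(x)
}
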