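#' Normalized entropy of a state sequence
#'
#' Shannon entropy of the sequence's state-occupancy distribution, divided
#' by the entropy of the alphabet (`log(alphabet_size)`), so the value lies
#' in `[0, 1]`: 0 for a constant sequence, 1 when the sequence spends an
#' equal number of periods in every alphabet state (attainable when the
#' sequence length is a multiple of the alphabet size). With `p_i` the
#' fraction of periods spent in state `i`,
#' `h = -sum(p_i * log(p_i)) / log(a)`; empty categories contribute zero.
#' The natural logarithm is used; normalization makes the base irrelevant.
#' Note this entropy measures the diversity of states, not their ordering:
#' it is invariant under permutation of the periods.
#'
#' @param states Character vector of states (one per period).
#' @param alphabet_size Number of states the sequence *can* take. Default 21
#'   (19 diagnostic categories plus `DEAD` and `EMIGRATED`); set 19 to score
#'   against the diagnostic alphabet only.
#' @return Normalized entropy in `[0, 1]`.
#' @examples
#' normalized_entropy(rep("SRD", 10))                      # 0
#' normalized_entropy(c(rep("SRD", 5), rep("PD", 5)))      # log(2)/log(21)
#' @export
normalized_entropy <- function(states, alphabet_size = 21) {
  if (alphabet_size < 2) stop("alphabet_size must be >= 2")
  states <- states[!is.na(states)]
  if (length(states) == 0) stop("empty sequence")
  p <- as.numeric(table(states)) / length(states)
  -sum(p * log(p)) / log(alphabet_size)
}

#' Per-person normalized entropy for a sequence table
#'
#' @param seqs A `diag_seqs` tibble.
#' @param alphabet_size See [normalized_entropy()].
#' @return Tibble `person_id`, `h`.
#' @export
sequence_entropy <- function(seqs, alphabet_size = 21) {
  m <- state_matrix(seqs)
  tibble::tibble(
    person_id = seqs$person_id,
    h = apply(m, 1, normalized_entropy, alphabet_size = alphabet_size)
  )
}

#' Stratum-level entropy summaries
#'
#' Mean and standard deviation of per-person normalized entropy by stratum.
#' Strata with fewer than `min_n` persons are flagged `suppressed`; rendered
#' output ([format_entropy_summary()]) masks their values while keeping the
#' count, so suppression never changes displayed totals.
#'
#' @param seqs A `diag_seqs` tibble.
#' @param by Stratifier columns (default D1 category and sex).
#' @param alphabet_size See [normalized_entropy()].
#' @param min_n Small-cell threshold (default 5).
#' @return Tibble with the stratifiers, `n`, `mean_h`, `sd_h`, `suppressed`.
#' @export
summarize_entropy <- function(seqs, by = c("d1_category", "sex"),
                              alphabet_size = 21, min_n = 5) {
  h <- sequence_entropy(seqs, alphabet_size)$h
  dat <- dplyr::bind_cols(seqs[by], tibble::tibble(h = h))
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n = dplyr::n(), mean_h = mean(.data$h),
                     sd_h = sd(.data$h), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  out$suppressed <- out$n < min_n
  out
}

#' @rdname summarize_entropy
#' @param summary Output of `summarize_entropy()`.
#' @return `format_entropy_summary()`: the same tibble with `mean_h`/`sd_h`
#'   set `NA` on suppressed rows.
#' @export
format_entropy_summary <- function(summary) {
  summary$mean_h[summary$suppressed] <- NA_real_
  summary$sd_h[summary$suppressed] <- NA_real_
  summary
}

#' Compare mean entropy across groups
#'
#' Two groups are compared with a Welch two-sample t-test (robust to unequal
#' variances); three or more with a one-way ANOVA. Groups with fewer than
#' two observations yield an explicit insufficient-data result rather than
#' an error. Typical uses: sex, age band at D1 (0-10 vs 11-17), parental
#' education, entry-year band.
#'
#' @param h Numeric vector of per-person entropies.
#' @param group Grouping vector, same length as `h`.
#' @return List of class `entropy_test`: `method` (`"welch_t"`, `"anova"` or
#'   `"insufficient_data"`), `statistic`, `df`, `p_value`, and a `groups`
#'   tibble (group, n, mean).
#' @export
compare_entropy_groups <- function(h, group) {
  stopifnot(length(h) == length(group))
  keep <- !is.na(h) & !is.na(group)
  h <- h[keep]
  group <- as.character(group)[keep]
  gtab <- tibble::tibble(group = sort(unique(group)))
  gtab$n <- vapply(gtab$group, function(g) sum(group == g), integer(1),
                   USE.NAMES = FALSE)
  gtab$mean_h <- vapply(gtab$group, function(g) mean(h[group == g]),
                        numeric(1), USE.NAMES = FALSE)
  result <- function(method, statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_) {
    structure(list(method = method, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value), groups = gtab),
              class = "entropy_test")
  }
  if (nrow(gtab) < 2 || any(gtab$n < 2)) {
    return(result("insufficient_data"))
  }
  if (nrow(gtab) == 2) {
    a <- h[group == gtab$group[1]]
    b <- h[group == gtab$group[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      # degenerate: no within-group variance; identical means -> t = 0
      tstat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
      return(result("welch_t", statistic = tstat,
                    df = length(h) - 2,
                    p_value = if (mean(a) == mean(b)) 1 else 0))
    }
    tt <- t.test(a, b, var.equal = FALSE)
    return(result("welch_t", tt$statistic, tt$parameter, tt$p.value))
  }
  fit <- aov(h ~ factor(group))
  s <- summary(fit)[[1]]
  result("anova", statistic = s[["F value"]][1],
         df = c(df1 = s[["Df"]][1], df2 = s[["Df"]][2]),
         p_value = s[["Pr(>F)"]][1])
}

#' @export
print.entropy_test <- function(x, ...) {
  cat("<entropy_test> method:", x$method, "\n")
  if (x$method == "welch_t") {
    cat("  t =", format(x$statistic), " df =", format(x$df),
        " p =", format(x$p_value), "\n")
  } else if (x$method == "anova") {
    cat("  F =", format(x$statistic), " df = (", paste(x$df, collapse = ", "),
        ") p =", format(x$p_value), "\n")
  }
  print(x$groups)
  invisible(x)
}
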