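test_that("bonferroni plan divides the family-wise alpha", {
  p1 <- bonferroni_plan(1)
  expect_equal(p1$alpha_adjusted, 0.05)
  expect_equal(p1$ci_level, 0.95)
  p180 <- bonferroni_plan(180)
  expect_equal(p180$alpha_adjusted, 0.05 / 180)
  expect_equal(p180$alpha_adjusted, 0.0002778, tolerance = 1e-4)
  expect_equal(bonferroni_plan(10)$alpha_adjusted, 0.005)
  expect_error(bonferroni_plan(0))
})

test_that("time-to-event rows follow the chapter and censoring rules", {
  rec <- dplyr::bind_rows(
    # D1 SRD (F3); F20.0 at day 400 -> event for outcome F2 at t = 400
    person_records("p1", "2005-03-10", "F32.1",
                   list(month = 0, day = 400, code = "F20.0")),
    # no post-D1 records -> censored at the 10-year horizon
    person_records("p2", "2005-03-10", "F43"),
    # emigration at day 200 before any SD -> censored at 200
    person_records("p3", "2005-03-10", "F43",
                   list(month = 0, day = 200, type = "EMIGRATION"))
  )
  rows <- make_time_to_event(rec, TAX, "SRD", "F2")
  rows <- rows[order(rows$person_id), ]
  expect_equal(rows$time, c(400, 3652, 200))
  expect_equal(rows$event, c(1L, 0L, 0L))
  expect_equal(rows$exposed, c(TRUE, FALSE, FALSE))
  expect_true(all(rows$time > 0))
})

test_that("a repeat of the D1 block never qualifies; a different block in the same chapter does", {
  rec <- dplyr::bind_rows(
    # D1 F32 (chapter F3); later F32.5 is a repeat, later F33 is an event
    person_records("p1", "2005-03-10", "F32",
                   list(month = 6, code = "F32.5"),
                   list(month = 20, code = "F33")),
    person_records("p2", "2005-03-10", "F43")
  )
  rows <- make_time_to_event(rec, TAX, "SRD", "F3")
  p1 <- rows[rows$person_id == "p1", ]
  expect_equal(p1$event, 1L)
  expect_gt(p1$time, 365)  # the F33, not the F32.5
  # with the sensitivity flag, same-chapter D1s are dropped
  rows2 <- make_time_to_event(rec, TAX, "SRD", "F3",
                              exclude_same_chapter = TRUE)
  expect_false("p1" %in% rows2$person_id)
})

test_that("death censors and increasing the horizon never loses events", {
  rec <- dplyr::bind_rows(
    person_records("p1", "2005-03-10", "F32",
                   list(month = 0, day = 150, type = "DEATH")),
    person_records("p2", "2005-03-10", "F43",
                   list(month = 0, day = 4000, code = "F20"))
  )
  rows10 <- make_time_to_event(rec, TAX, "SRD", "F2")
  expect_equal(rows10$time[rows10$person_id == "p1"], 150)
  expect_equal(sum(rows10$event), 0)  # the F20 falls beyond the horizon
  rows12 <- make_time_to_event(rec, TAX, "SRD", "F2", horizon_days = 4200)
  expect_gte(sum(rows12$event), sum(rows10$event))
  expect_equal(sum(rows12$event), 1L)
})

test_that("ordering sanity: all exposed events early implies HR > 1", {
  rows <- tibble::tibble(
    person_id = paste0("p", 1:4),
    sex = "F",
    exposed = c(TRUE, TRUE, FALSE, FALSE),
    time = c(10, 20, 300, 400),
    event = c(1L, 1L, 1L, 1L)
  )
  # complete separation in time: the partial likelihood is monotone, so the
  # fitter warns about a possibly infinite coefficient — expected here
  fit <- suppressWarnings(fit_hazard_contrast(rows, ci_level = 0.95))
  expect_equal(fit$flag, "ok")
  expect_gt(fit$hr, 1)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("matches a reference Efron-ties fit", {
  set.seed(8)
  n <- 400
  rows <- tibble::tibble(
    person_id = paste0("p", seq_len(n)),
    sex = "F",
    exposed = rep(c(TRUE, FALSE), each = n / 2),
    time = ceiling(rexp(n, rate = ifelse(rep(c(TRUE, FALSE), each = n / 2),
                                         0.02, 0.01))),
    event = 1L
  )
  rows$event[rows$time > 100] <- 0L
  rows$time <- pmin(rows$time, 100)
  fit <- fit_hazard_contrast(rows, ci_level = 0.999)
  ref <- survival::coxph(survival::Surv(time, event) ~ exposed, data = rows,
                         ties = "efron")
  ci <- exp(confint(ref, level = 0.999))
  expect_equal(fit$hr, unname(exp(coef(ref))), tolerance = 1e-10)
  expect_equal(fit$ci_low, unname(ci[1]), tolerance = 1e-8)
  expect_equal(fit$ci_high, unname(ci[2]), tolerance = 1e-8)
})

test_that("degenerate contrasts are flagged, not thrown", {
  rows <- tibble::tibble(person_id = c("a", "b"), sex = "F",
                         exposed = c(TRUE, FALSE), time = c(10, 20),
                         event = c(0L, 0L))
  expect_equal(fit_hazard_contrast(rows)$flag, "no_events")
  rows$event <- c(1L, 0L)
  expect_equal(fit_hazard_contrast(rows)$flag, "no_events_in_arm")
  rows$exposed <- c(TRUE, TRUE)
  expect_equal(fit_hazard_contrast(rows)$flag, "empty_arm")
})

test_that("the contrast grid derives its plan from attempted tests", {
  cc <- cohort_config(400, transition_matrix = default_transition_matrix(
    default_d1_calibration()$category, stay = 0.7), seed = 19)
  sim <- generate_cohort(cc, TAX)
  grid <- hazard_contrast_grid(sim$records, TAX, per_sex = TRUE,
                               chapters = c("F3", "F4", "F8", "F9"))
  expect_s3_class(grid$contrasts, "tbl_df")
  expect_true(all(grid$contrasts$flag %in%
                    c("ok", "empty_arm", "no_events_in_arm", "no_events")))
  expect_equal(grid$plan$ci_level, 1 - 0.05 / grid$plan$n_tests)
  ok <- grid$contrasts[grid$contrasts$flag == "ok", ]
  expect_true(all(ok$ci_low <= ok$hr & ok$hr <= ok$ci_high))
  expect_true(all(ok$hr > 0))
})
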