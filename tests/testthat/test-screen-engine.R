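test_that("lms_z matches the Box-Cox closed form and its log-normal limit", {
  expect_equal(lms_z(16, L = -1.6, M = 16, S = 0.08), 0)
  expect_equal(lms_z(16 * 1.08, L = 1, M = 16, S = 0.08), 1)
  # frozen value of ((14/16)^-1.6 - 1) / (-1.6 * 0.08), evaluated directly
  expect_equal(lms_z(14, L = -1.6, M = 16, S = 0.08), -1.86085543184,
               tolerance = 1e-10)
  # continuity in L at 0
  v <- 14.3
  expect_lt(abs(lms_z(v, L = 1e-8, M = 16, S = 0.08) -
                  log(v / 16) / 0.08), 1e-6)
  expect_error(lms_z(0, L = 1, M = 16, S = 0.08), "positive")
  expect_error(lms_z(-2, L = 1, M = 16, S = 0.08), "positive")
  expect_error(lms_z(14, L = 1, M = -1, S = 0.08), "LMS")
})

test_that("anthropometric flag is strict at -1 and branch-independent", {
  expect_true(anthropometric_element(-1.5))
  expect_false(anthropometric_element(-1))   # strict inequality boundary
  expect_true(anthropometric_element(-2.3))
  expect_false(anthropometric_element(0.4))
  expect_error(anthropometric_element(NA_real_), "finite")
  # the threshold does not depend on which reference the age selects
  expect_identical(anthro_reference(c(1, 1.99, 2, 3)),
                   c("weight_for_length", "weight_for_length",
                     "bmi_for_age", "bmi_for_age"))
  for (z in c(-3, -1.01, -1, -0.99, 0, 2)) {
    expect_identical(anthropometric_element(z), anthropometric_element(z))
    # same z flagged identically whether the patient is 1.9 or 2.1 years old
    expect_identical(z < -1, anthropometric_element(z))
  }
})

test_that("daily elements are pure predicates of their inputs", {
  inputs <- data.frame(
    on_enteral_nutrition = c(FALSE, TRUE, FALSE, FALSE),
    on_parenteral_nutrition = c(TRUE, FALSE, FALSE, FALSE),
    intubated = c(FALSE, TRUE, FALSE, FALSE),
    n_food_allergies = c(0, 1, 2, NA),
    anthro_z = c(-0.5, -1.2, -1, 0),
    rd_identified_risk = c(FALSE, FALSE, TRUE, NA),
    pnst_positive = c(FALSE, TRUE, FALSE, FALSE)
  )
  out <- evaluate_daily(inputs)
  expect_identical(names(out), cwnst_elements("daily"))
  expect_identical(out$parenteral_nutrition, c(1L, 0L, 0L, 0L))
  expect_identical(out$enteral_nutrition, c(0L, 1L, 0L, 0L))
  expect_identical(out$intubation, c(0L, 1L, 0L, 0L))
  expect_identical(out$food_allergies_2plus, c(0L, 0L, 1L, 0L))  # >= 2 fires
  expect_identical(out$anthropometric_flag, c(0L, 1L, 0L, 0L))   # strict < -1
  expect_identical(out$rd_identified_risk, c(0L, 0L, 1L, 0L))
  expect_identical(out$pnst_positive, c(0L, 1L, 0L, 0L))

  all_neg <- evaluate_daily(data.frame(
    on_enteral_nutrition = FALSE, on_parenteral_nutrition = FALSE,
    intubated = FALSE, n_food_allergies = 0, anthro_z = 0,
    rd_identified_risk = FALSE, pnst_positive = FALSE))
  expect_true(all(all_neg == 0L))
  expect_error(evaluate_daily(data.frame(anthro_z = 1)), "missing column")
})

test_that("missing anthropometry yields a negative flag with a warning", {
  inputs <- data.frame(
    on_enteral_nutrition = FALSE, on_parenteral_nutrition = FALSE,
    intubated = FALSE, n_food_allergies = 0, anthro_z = NA_real_,
    rd_identified_risk = FALSE, pnst_positive = FALSE)
  expect_warning(out <- evaluate_daily(inputs), "missing anthropometry")
  expect_identical(out$anthropometric_flag, 0L)
})

test_that("status-change flags require three or more sustained days", {
  # three consecutive low-intake days before a day-4 evaluation
  f <- evaluate_status_change(intake_fraction = c(0.4, 0.4, 0.4),
                              npo = rep(FALSE, 3), weight_kg = rep(10, 3),
                              day = 4)
  expect_true(f[["intake_lt50_3d"]])
  expect_false(f[["npo_gt3d"]])
  expect_false(f[["weight_loss_ge5pct"]])
  # exactly two NPO days is below the streak length
  f2 <- evaluate_status_change(intake_fraction = rep(1, 4),
                               npo = c(FALSE, FALSE, TRUE, TRUE),
                               weight_kg = rep(10, 4), day = 4)
  expect_false(f2[["npo_gt3d"]])
  # a 6% loss from the admission maximum held three days
  f3 <- evaluate_status_change(intake_fraction = rep(1, 4),
                               npo = rep(FALSE, 4),
                               weight_kg = c(10, 9.4, 9.4, 9.4), day = 4)
  expect_true(f3[["weight_loss_ge5pct"]])
  # exactly 5% counts (the threshold is inclusive)
  f4 <- evaluate_status_change(intake_fraction = rep(1, 4),
                               npo = rep(FALSE, 4),
                               weight_kg = c(10, 9.5, 9.5, 9.5), day = 4)
  expect_true(f4[["weight_loss_ge5pct"]])
  # an interrupted streak does not fire
  f5 <- evaluate_status_change(intake_fraction = c(0.4, 0.9, 0.4, 0.4),
                               npo = rep(FALSE, 4),
                               weight_kg = rep(10, 4), day = 4)
  expect_false(f5[["intake_lt50_3d"]])
})

test_that("off-schedule status-change evaluation errors unless permissive", {
  sched <- status_change_days(as.Date("2019-03-04"), horizon = 14)
  expect_error(
    evaluate_status_change(rep(1, 3), rep(FALSE, 3), rep(10, 3), day = 3,
                           scheduled_days = sched),
    "not a scheduled"
  )
  expect_warning(
    evaluate_status_change(rep(1, 3), rep(FALSE, 3), rep(10, 3), day = 3,
                           scheduled_days = sched, permissive = TRUE),
    "not a scheduled"
  )
})

test_that("status-change schedule walks day 4 then Mon/Wed/Fri", {
  # Monday admission: day 4 is Thursday, then Fri(5), Mon(8), Wed(10)
  expect_identical(status_change_days(as.Date("2019-03-04"), 10),
                   c(4L, 5L, 8L, 10L))
  # too short a stay: nothing scheduled before day 4
  expect_identical(status_change_days(as.Date("2019-03-04"), 3), integer(0))
  # Sunday admission: day 4 is a Wednesday, listed once only
  d <- status_change_days(as.Date("2019-03-03"), 10)
  expect_identical(d, c(4L, 6L, 9L))
  expect_false(any(duplicated(d)))
  # all scheduled days lie in the horizon and are ascending
  for (adm in as.Date("2019-06-01") + 0:6) {
    s <- status_change_days(adm, 21)
    expect_true(all(s >= 4 & s <= 21))
    expect_identical(s, sort(s))
  }
})

test_that("any-positive aggregation is monotone in the element subset", {
  vec <- data.frame(enteral_nutrition = 1L, parenteral_nutrition = 0L,
                    pnst_positive = 0L, intubation = 0L)
  expect_true(screen_positive(vec, c("enteral_nutrition", "pnst_positive")))
  expect_false(screen_positive(vec, "pnst_positive"))
  expect_error(screen_positive(vec, character(0)), "nonempty")
  expect_error(screen_positive(vec, "not_an_element"), "unknown element")

  set.seed(7)
  elements <- cwnst_elements("daily")
  cohort <- as.data.frame(matrix(rbinom(20 * 7, 1, 0.3), 20,
                                 dimnames = list(NULL, elements)))
  for (i in 1:25) {
    small <- sample(elements, sample(1:6, 1))
    big <- union(small, sample(elements, sample(1:7, 1)))
    p_small <- screen_positive(cohort, small)
    p_big <- screen_positive(cohort, big)
    expect_true(all(p_big >= p_small))  # adding elements never unflags
  }
  all_false <- as.data.frame(matrix(0L, 1, 7,
                                    dimnames = list(NULL, elements)))
  expect_false(screen_positive(all_false, elements))
})
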