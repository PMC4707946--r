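test_that("default specs carry the published doses, reach and retention", {
  sp <- default_intervention_specs()
  expect_setequal(sp$component_id,
                  c("ASAP1", "ASAP2", "ASAP3", "DrinkRight", "MoveMore",
                    "SnackSmart"))
  expect_equal(sp["ASAP1", c("dose_minutes", "dose_met")],
               data.frame(dose_minutes = 40, dose_met = 2.99,
                          row.names = "ASAP1"))
  expect_equal(sp["ASAP2", "dose_minutes"], 10)
  expect_equal(sp["ASAP2", "dose_met"], 2.62)
  expect_equal(sp["ASAP3", "dose_minutes"], 30)
  expect_equal(sp["ASAP3", "dose_met"], 4.96)
  expect_equal(sp["DrinkRight", "dose_kcal"], -60)
  expect_equal(sp["SnackSmart", "dose_kcal"], -68.25)
  expect_equal(sp["MoveMore", c("dose_minutes", "dose_met")],
               data.frame(dose_minutes = 15, dose_met = 4.5,
                          row.names = "MoveMore"))
  expect_equal(sp$reach, c(0.10, 0.90, 0.75, 0.15, 0.15, 0.15))
  # exactly one dose family per component
  activity <- !is.na(sp$dose_minutes) & !is.na(sp$dose_met)
  dietary <- !is.na(sp$dose_kcal)
  expect_true(all(xor(activity, dietary)))
  expect_true(all(sp$reach >= 0 & sp$reach <= 1))
  expect_true(all(sp$retention >= 0 & sp$retention <= 1))
})

test_that("the two retention presets differ as documented", {
  text <- default_intervention_specs("step4-text")
  tab <- default_intervention_specs("table1")
  expect_equal(text[c("ASAP1", "ASAP2", "ASAP3"), "retention"],
               c(0.80, 0.80, 0.90))
  expect_equal(tab[c("ASAP1", "ASAP2", "ASAP3"), "retention"],
               c(0.80, 0.90, 0.80))
  expect_equal(text["DrinkRight", "retention"], 0.80)
  expect_identical(text[c("DrinkRight", "MoveMore", "SnackSmart"), ],
                   tab[c("DrinkRight", "MoveMore", "SnackSmart"), ])
})

test_that("enrollment respects reach, retention, and eligibility", {
  b <- default_bundle()
  pop <- create_population(10000, town_profile("A", b), b, seed = 13)
  sp <- default_intervention_specs()

  # reach = 1, retention = 1: everyone in, nobody out
  full <- sp["ASAP2", ]; full$reach <- 1; full$retention <- 1
  enr <- assign_enrollment(pop, full, seed = 1)
  expect_true(all(enr$enrolled))
  expect_true(all(is.na(enr$dropout_day)))

  # reach = 0: nobody in
  none <- sp["ASAP2", ]; none$reach <- 0
  expect_false(any(assign_enrollment(pop, none, seed = 1)$enrolled))

  # binomial reach at the default 90%
  enr2 <- assign_enrollment(pop, sp["ASAP2", ], seed = 2)
  se <- sqrt(0.9 * 0.1 / nrow(pop))
  expect_lt(abs(mean(enr2$enrolled) - 0.9), 3 * se)

  # dropout flagged at 1 - retention among the enrolled
  p_drop <- 1 - sp["ASAP2", "retention"]
  dropped <- !is.na(enr2$dropout_day[enr2$enrolled])
  se_d <- sqrt(p_drop * (1 - p_drop) / sum(enr2$enrolled))
  expect_lt(abs(mean(dropped) - p_drop), 3 * se_d)
  expect_true(all(enr2$dropout_day >= 1 & enr2$dropout_day <= 365,
                  na.rm = TRUE))

  # community components never enroll non-attendees
  hkos <- assign_enrollment(pop, sp["MoveMore", ], seed = 3)
  expect_false(any(hkos$enrolled & !pop$attends_afterschool))

  # deterministic for a fixed seed
  expect_identical(assign_enrollment(pop, sp["ASAP3", ], seed = 4),
                   assign_enrollment(pop, sp["ASAP3", ], seed = 4))
})

test_that("an agent active on day d was active on every earlier day", {
  b <- default_bundle()
  pop <- create_population(500, town_profile("A", b), b, seed = 17)
  sp <- default_intervention_specs()["ASAP1", ]
  sp$reach <- 1; sp$retention <- 0.5
  enr <- assign_enrollment(pop, sp, seed = 5)
  act <- vapply(1:365, function(d) enrollment_active(enr, d),
                logical(nrow(enr)))
  # once inactive, never active again
  expect_true(all(apply(act, 1, function(x) all(diff(as.integer(x)) <= 0))))
  expect_true(all(act[, 1] == enr$enrolled | enr$dropout_day == 1L,
                  na.rm = TRUE))
})

test_that("dietary doses add up and respect attendance", {
  sp <- default_intervention_specs()
  expect_equal(apply_dietary_dose(sp, "DrinkRight", attends = TRUE), -60)
  expect_equal(apply_dietary_dose(sp, "SnackSmart", attends = TRUE), -68.25)
  expect_equal(apply_dietary_dose(sp, c("DrinkRight", "SnackSmart"),
                                  attends = TRUE), -128.25)
  # activity components contribute no kcal adjustment
  expect_equal(apply_dietary_dose(sp, c("MoveMore", "ASAP3"),
                                  attends = TRUE), 0)
  expect_equal(apply_dietary_dose(sp, c("DrinkRight", "SnackSmart"),
                                  attends = FALSE), 0)
  expect_equal(apply_dietary_dose(sp, character(0), attends = TRUE), 0)
})
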