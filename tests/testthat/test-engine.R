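test_that("invalid configurations fail before any simulation work", {
  expect_error(simulation_config(n_agents = 0), "n_agents")
  expect_error(simulation_config(n_days = 0), "n_days")
  expect_error(simulation_config(enabled = "ASAP9"), "unknown intervention")
  expect_error(simulation_config(seed = 2^31), "seed")
  expect_error(simulation_config(afterschool_fraction = 1.2), "\\[0, 1\\]")
  # HKOS shorthand expands to the three out-of-school components
  cfg <- simulation_config(enabled = c("ASAP1", "HKOS"))
  expect_setequal(cfg$enabled,
                  c("ASAP1", "DrinkRight", "MoveMore", "SnackSmart"))
})

test_that("a multiplier pinned to baseline PAL forces zero surplus", {
  b <- equilibrium_bundle()
  cfg <- simulation_config("A", n_agents = 100, n_days = 1, seed = 3,
                           afterschool_fraction = 0, bundle = b,
                           record_ledgers = TRUE)
  res <- run_simulation(cfg)
  expect_equal(res$summary$mean_calorie_surplus_kcal, 0, tolerance = 1e-9)
  expect_equal(max(abs(res$ledgers$calorie_gap_kcal)), 0, tolerance = 1e-9)
  expect_equal(res$population$weight_kg, res$population_init$weight_kg,
               tolerance = 1e-12)
})

test_that("identical configurations reproduce bit-identical results", {
  cfg <- simulation_config("B", n_agents = 150, n_days = 30, seed = 42,
                           enabled = c("ASAP2", "HKOS"))
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$enrollments, r2$enrollments)
})

test_that("engine day-1 physiology matches the minute-level timeline path", {
  b <- default_bundle()
  sp <- specs_full_coverage()
  cfg <- simulation_config("A", n_agents = 40, n_days = 1, seed = 8,
                           enabled = c("ASAP3", "HKOS"), specs = sp,
                           bundle = b, record_ledgers = TRUE)
  res <- run_simulation(cfg)
  pop0 <- res$population_init
  prof <- town_profile("A", b)
  led <- res$ledgers[res$ledgers$day == 1, ]
  for (i in seq_len(nrow(pop0))) {
    agent <- pop0[i, ]
    active <- c("ASAP3",
                if (agent$attends_afterschool)
                  c("DrinkRight", "MoveMore", "SnackSmart"))
    tl <- build_day_timeline(agent, prof, b,
                             interventions = sp[sp$component_id %in% active, ])
    expect_equal(led$pal[i], compute_pal(tl$met))
    rmr <- schofield_rmr(agent$sex, agent$age_days / 365, agent$weight_kg,
                         agent$height_cm)
    expect_equal(led$expenditure_kcal[i],
                 total_energy_expenditure(rmr, compute_pal(tl$met)))
    adj <- apply_dietary_dose(sp, active, agent$attends_afterschool)
    expect_equal(led$intake_kcal[i],
                 daily_intake(rmr, agent$intake_multiplier, adj))
    # hourly ticks sum to the daily expenditure
    hourly_tee <- rmr / 1440 * met_minutes_by_hour(tl)
    expect_equal(sum(hourly_tee), led$expenditure_kcal[i])
  }
})

test_that("mass bookkeeping closes over a multi-week run", {
  cfg <- simulation_config("A", n_agents = 200, n_days = 120, seed = 6,
                           enabled = "ASAP2", record_ledgers = TRUE)
  res <- run_simulation(cfg)
  gains <- tapply(res$ledgers$calorie_gap_kcal, res$ledgers$agent_id, sum)
  audit <- res$population$weight_kg - res$population_init$weight_kg
  expect_equal(as.vector(gains[as.character(res$population$id)]) / KCAL_PER_KG,
               audit, tolerance = 1e-9)
  expect_equal(res$gap_total_kcal / KCAL_PER_KG, audit, tolerance = 1e-12)
})

test_that("daily summaries aggregate the ledger and classify by sex", {
  b <- default_bundle()
  pop <- create_population(1, town_profile("A", b), b, seed = 30)
  ledger <- data.frame(intake_kcal = 1600, expenditure_kcal = 1500,
                       calorie_gap_kcal = 100, pal = 1.5)
  s <- summarize_day(pop, ledger, b, day = 1)
  expect_equal(s$mean_calorie_surplus_kcal, 100)
  expect_equal(s$mean_intake_kcal, 1600)
  expect_equal(s$mean_bmi, pop$bmi)

  # an all-female population reports zero male percentages, flagged by count
  popf <- create_population(50, town_profile("A", b), b, seed = 31)
  popf$sex <- "female"
  ledf <- data.frame(intake_kcal = rep(1600, 50),
                     expenditure_kcal = rep(1500, 50),
                     calorie_gap_kcal = rep(100, 50), pal = rep(1.5, 50))
  sf <- summarize_day(popf, ledf, b, day = 1)
  expect_equal(sf$pct_obese_male, 0)
  expect_equal(sf$pct_overweight_male, 0)
  expect_equal(sf$n_male, 0L)
  expect_equal(sf$n_female, 50L)

  expect_error(summarize_day(popf, ledf[1:10, ], b), "every agent")
})

test_that("summary series has one row per day with consistent columns", {
  cfg <- simulation_config("C", n_agents = 80, n_days = 25, seed = 12)
  res <- run_simulation(cfg)
  s <- res$summary
  expect_equal(nrow(s), 25L)
  expect_equal(s$day, 1:25)
  expect_equal(s$mean_calorie_surplus_kcal,
               s$mean_intake_kcal - s$mean_dee_kcal, tolerance = 1e-9)
  pcts <- unlist(s[, grep("^pct_", names(s))])
  expect_true(all(pcts >= 0 & pcts <= 100))
})

test_that("doubling the population barely moves the final mean BMI", {
  r1 <- run_simulation(simulation_config("A", n_agents = 600, n_days = 365,
                                         seed = 9))
  r2 <- run_simulation(simulation_config("A", n_agents = 1200, n_days = 365,
                                         seed = 9))
  se <- sd(r1$population$bmi) / sqrt(600)
  expect_lt(abs(r1$summary$mean_bmi[365] - r2$summary$mean_bmi[365]), 3 * se)
})

test_that("results are written as documented files", {
  cfg <- simulation_config("A", n_agents = 30, n_days = 5, seed = 2,
                           enabled = "MoveMore", record_ledgers = TRUE)
  res <- run_simulation(cfg)
  dir <- withr::local_tempdir()
  write_result(res, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "population_final.csv")))
  expect_true(file.exists(file.path(dir, "config_echo.json")))
  expect_true(file.exists(file.path(dir, "ledgers.csv")))
  echo <- jsonlite::read_json(file.path(dir, "config_echo.json"))
  expect_equal(echo$seed, 2L)
  expect_equal(echo$town_type, "A")
  s <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(s), 5L)
})

test_that("aging past the reference grid raises a named range error", {
  b <- default_bundle()
  keep <- b$lms$age_months <= 157
  b$lms <- b$lms[keep, ]
  b$growth <- b$growth[b$growth$age_months <= 157, ]
  cfg <- simulation_config("A", n_agents = 100, n_days = 365, seed = 14,
                           bundle = b)
  expect_error(run_simulation(cfg), "reference grid exhausted: agent")
})
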