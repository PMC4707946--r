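## Simulation engine: configuration, the daily loop (activity realization,
## energy settlement at midnight, height growth), per-day summaries matching
## the monitor outputs (mean BMI, intake, DEE, calorie surplus, weight-status
## percentages by sex), and result I/O.

#' Build and validate a simulation configuration
#'
#' @param town_type `"A"`, `"B"` or `"C"`.
#' @param n_agents Number of agents (>= 1).
#' @param n_days Run length in days (default 365).
#' @param seed Integer seed; all randomness in the run derives from it
#'   (population first, school-program assignment second, per-component
#'   enrollment third). Must be below 2^31 - 100.
#' @param afterschool_fraction Fraction of agents attending the after-school
#'   community program (default 0.15).
#' @param enabled Character vector of enabled intervention components, a
#'   subset of `ASAP1, ASAP2, ASAP3, DrinkRight, MoveMore, SnackSmart`.
#'   `"HKOS"` is accepted as shorthand for all three out-of-school
#'   components.
#' @param specs Intervention spec table (default
#'   [default_intervention_specs()]); override rows to change dose, reach or
#'   retention.
#' @param bundle A `reference_bundle`, a path to a bundle JSON file, or
#'   `NULL` to generate the synthetic default bundle from `seed`.
#' @param bmi_current_offset Town-A BMI median offset above the reference
#'   median, kg/m^2 (default 1.0).
#' @param weight_floor_kg Minimum weight, kg (default 10); hitting it warns.
#' @param n_homes,n_schools,n_communities Environment sizes (56, 12, 1).
#' @param asap_exclusive Should each school run at most one enabled ASAP
#'   program (default `TRUE`)? If `FALSE`, every school runs all enabled
#'   programs.
#' @param record_ledgers Keep the per-agent per-day ledger (default `FALSE`;
#'   memory grows as `n_agents * n_days`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(town_type = c("A", "B", "C"),
                              n_agents = 100L,
                              n_days = 365L,
                              seed = 1L,
                              afterschool_fraction = 0.15,
                              enabled = character(0),
                              specs = default_intervention_specs(),
                              bundle = NULL,
                              bmi_current_offset = 1.0,
                              weight_floor_kg = 10,
                              n_homes = 56L,
                              n_schools = 12L,
                              n_communities = 1L,
                              asap_exclusive = TRUE,
                              record_ledgers = FALSE) {
  town_type <- match.arg(town_type)
  if (!is.numeric(n_agents) || n_agents < 1) {
    stop("n_agents must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_days) || n_days < 1) {
    stop("n_days must be >= 1", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || abs(seed) >= 2^31 - 100) {
    stop("seed must be a single integer below 2^31 - 100", call. = FALSE)
  }
  if (afterschool_fraction < 0 || afterschool_fraction > 1) {
    stop("afterschool_fraction must lie in [0, 1]", call. = FALSE)
  }
  if ("HKOS" %in% enabled) {
    enabled <- union(setdiff(enabled, "HKOS"),
                     c("DrinkRight", "MoveMore", "SnackSmart"))
  }
  if (!all(enabled %in% COMPONENTS)) {
    stop("unknown intervention component(s): ",
         paste(setdiff(enabled, COMPONENTS), collapse = ", "), call. = FALSE)
  }
  if (any(n_homes < 1, n_schools < 1, n_communities < 1)) {
    stop("environment counts must be >= 1", call. = FALSE)
  }
  structure(list(
    town_type = town_type,
    n_agents = as.integer(n_agents),
    n_days = as.integer(n_days),
    seed = as.integer(seed),
    afterschool_fraction = afterschool_fraction,
    enabled = enabled,
    specs = specs,
    bundle = bundle,
    bmi_current_offset = bmi_current_offset,
    weight_floor_kg = weight_floor_kg,
    n_homes = as.integer(n_homes),
    n_schools = as.integer(n_schools),
    n_communities = as.integer(n_communities),
    asap_exclusive = isTRUE(asap_exclusive),
    record_ledgers = isTRUE(record_ledgers)
  ), class = "simulation_config")
}

resolve_bundle <- function(config) {
  b <- config$bundle
  if (is.null(b)) return(generate_reference_bundle(seed = config$seed))
  if (inherits(b, "reference_bundle")) return(b)
  if (is.character(b) && length(b) == 1L) return(read_bundle(b))
  stop("bundle must be NULL, a reference_bundle, or a file path",
       call. = FALSE)
}

#' Summarize one simulated day
#'
#' Population means of the day's ledger plus weight-status percentages by
#' sex, classified against the reference (town-unshifted) LMS distribution.
#' Overweight excludes obese (85th-95th percentile). An empty sex stratum
#' reports 0 percentages; its emptiness is visible in `n_male` / `n_female`.
#'
#' @param population An `obesim_population` (state at the end of the day).
#' @param ledger Data frame with one row per agent for the day: columns
#'   `intake_kcal`, `expenditure_kcal`, `calorie_gap_kcal`, `pal`.
#' @param bundle A `reference_bundle`.
#' @param day Day index stored in the summary row.
#' @return One-row data frame (a `DailySummary`).
#' @export
summarize_day <- function(population, ledger, bundle, day = NA_integer_) {
  if (nrow(ledger) != nrow(population)) {
    stop("ledger must cover every agent exactly once (", nrow(ledger),
         " rows for ", nrow(population), " agents)", call. = FALSE)
  }
  status <- classify_weight_status(population, bundle)
  male <- population$sex == "male"
  pct <- function(st, stratum) {
    if (!any(stratum)) return(0)
    100 * mean(status[stratum] == st)
  }
  data.frame(
    day = day,
    mean_bmi = mean(population$bmi),
    mean_intake_kcal = mean(ledger$intake_kcal),
    mean_dee_kcal = mean(ledger$expenditure_kcal),
    mean_calorie_surplus_kcal = mean(ledger$calorie_gap_kcal),
    mean_pal = mean(ledger$pal),
    pct_overweight_male = pct("overweight", male),
    pct_overweight_female = pct("overweight", !male),
    pct_obese_male = pct("obese", male),
    pct_obese_female = pct("obese", !male),
    n_male = sum(male),
    n_female = sum(!male)
  )
}

#' Run the simulation
#'
#' Generates the population, assigns intervention enrollment, then iterates
#' the daily loop: realize each agent's minute-resolution activity (baseline
#' pattern plus active intervention bouts replacing sedentary time), compute
#' PAL, total energy expenditure (RMR x PAL) and intake (RMR x multiplier
#' plus dietary doses), settle the calorie gap into weight at 7,700 kcal/kg
#' at midnight, grow height, and emit a daily summary. Bit-reproducible for a
#' fixed configuration.
#'
#' @param config A [simulation_config()].
#' @return An object of class `obesim_result`: list with `config`, `summary`
#'   (one row per day), `population` (final state), `population_init`,
#'   `enrollments`, `ledgers` (if recorded), `log` (character vector of
#'   run warnings).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  bundle <- resolve_bundle(config)
  profile <- town_profile(config$town_type, bundle,
                          config$bmi_current_offset)
  specs <- config$specs
  enabled <- config$enabled
  n <- config$n_agents

  pop <- create_population(n, profile, bundle, seed = config$seed,
                           afterschool_fraction = config$afterschool_fraction,
                           n_homes = config$n_homes,
                           n_schools = config$n_schools)
  pop_init <- pop
  log <- character(0)

  ## School-program assignment: by default each school runs at most one of
  ## the enabled ASAP programs.
  asap_on <- intersect(c("ASAP1", "ASAP2", "ASAP3"), enabled)
  school_prog <- rep(NA_character_, config$n_schools)
  if (length(asap_on) > 0L && config$asap_exclusive) {
    set.seed(config$seed + 7L)
    school_prog <- sample(rep_len(asap_on, config$n_schools))
  }

  ## Enrollment matrices: n x component.
  enrolled <- matrix(FALSE, n, length(COMPONENTS),
                     dimnames = list(NULL, COMPONENTS))
  dropout <- matrix(Inf, n, length(COMPONENTS),
                    dimnames = list(NULL, COMPONENTS))
  enr_list <- list()
  for (j in seq_along(COMPONENTS)) {
    comp <- COMPONENTS[j]
    if (!comp %in% enabled) next
    spec <- specs[specs$component_id == comp, , drop = FALSE]
    elig <- NULL
    if (comp %in% asap_on && config$asap_exclusive) {
      elig <- school_prog[pop$school_id] == comp
      elig[is.na(elig)] <- FALSE
    }
    enr <- assign_enrollment(pop, spec, seed = config$seed + 10L + j,
                             eligible = elig)
    enrolled[, comp] <- enr$enrolled
    dropout[, comp] <- ifelse(is.na(enr$dropout_day), Inf, enr$dropout_day)
    enr_list[[comp]] <- enr
  }
  enrollments <- if (length(enr_list)) do.call(rbind, enr_list) else NULL
  if (!is.null(enrollments)) rownames(enrollments) <- NULL

  ## Precompute fast lookup matrices over the bundle grid.
  rng <- bundle_age_range(bundle)
  n_ages <- rng[2] - rng[1] + 1L
  Vmat <- matrix(NA_real_, n_ages, 2)
  Vmat[cbind(bundle$growth$age_months - rng[1] + 1L,
             ifelse(bundle$growth$sex == "male", 1L, 2L))] <-
    bundle$growth$height_velocity

  ## Baseline MET-minutes and per-segment sedentary budgets for this town.
  pat <- activity_pattern(bundle, config$town_type)
  base_mm <- baseline_met_minutes(pat)
  sed_budget <- segment_sedentary(pat)
  act_specs <- specs[specs$type == "activity" &
                       specs$component_id %in% enabled, , drop = FALSE]
  diet_specs <- specs[specs$type == "dietary" &
                        specs$component_id %in% enabled, , drop = FALSE]

  attends <- pop$attends_afterschool
  base_agent <- ifelse(attends, base_mm[["attendee"]],
                       base_mm[["non_attendee"]])

  n_days <- config$n_days
  summary_rows <- vector("list", n_days)
  if (config$record_ledgers) {
    led_intake <- matrix(NA_real_, n, n_days)
    led_tee <- matrix(NA_real_, n, n_days)
    led_pal <- matrix(NA_real_, n, n_days)
  }
  gap_total <- numeric(n)
  floor_hits <- 0L
  trunc_bouts <- 0L

  sex_idx <- ifelse(pop$sex == "male", 1L, 2L)
  diet_dose <- if (nrow(diet_specs))
    setNames(diet_specs$dose_kcal, diet_specs$component_id) else numeric(0)

  check_grid <- function(months) {
    if (max(months) > rng[2]) {
      bad <- which(months > rng[2])[1]
      stop("reference grid exhausted: agent ", pop$id[bad], " reached ",
           months[bad], " months (grid ends at ", rng[2], ")",
           call. = FALSE)
    }
  }
  for (day in seq_len(n_days)) {
    months <- age_days_to_months(pop$age_days)
    check_grid(months)
    ij <- cbind(months - rng[1] + 1L, sex_idx)
    rmr <- schofield_rmr(pop$sex, pop$age_days / 365, pop$weight_kg,
                         pop$height_cm)

    ## Activity realization: baseline + active intervention bouts replacing
    ## sedentary minutes in their window segment.
    met_min <- base_agent
    if (nrow(act_specs)) {
      rem <- matrix(rep(sed_budget, each = n), n, length(sed_budget),
                    dimnames = list(NULL, names(sed_budget)))
      rem[!attends, "community"] <- 0
      for (k in seq_len(nrow(act_specs))) {
        comp <- act_specs$component_id[k]
        active <- enrolled[, comp] & day < dropout[, comp]
        if (comp %in% c("MoveMore")) active <- active & attends
        if (!any(active)) next
        seg <- act_specs$window[k]
        eff <- pmin(act_specs$dose_minutes[k], rem[, seg])
        eff[!active] <- 0
        short <- active & eff < act_specs$dose_minutes[k]
        if (any(short)) trunc_bouts <- trunc_bouts + sum(short)
        rem[, seg] <- rem[, seg] - eff
        met_min <- met_min + eff * (act_specs$dose_met[k] - MET_SEDENTARY)
      }
    }
    pal <- met_min / 1440
    tee <- rmr * pal

    ## Intake: RMR multiple plus dietary doses for active attendees.
    adj <- numeric(n)
    for (comp in names(diet_dose)) {
      active <- enrolled[, comp] & day < dropout[, comp] & attends
      adj[active] <- adj[active] + diet_dose[[comp]]
    }
    intake <- pmax(0, rmr * pop$intake_multiplier + adj)
    gap <- intake - tee
    gap_total <- gap_total + gap

    ## Midnight settlement: weight, then uncoupled height growth and aging.
    new_w <- pop$weight_kg + gap / KCAL_PER_KG
    below <- new_w < config$weight_floor_kg
    if (any(below)) {
      floor_hits <- floor_hits + sum(below)
      new_w <- pmax(new_w, config$weight_floor_kg)
    }
    pop$weight_kg <- new_w
    pop$height_cm <- pop$height_cm + Vmat[ij]
    pop$age_days <- pop$age_days + 1L
    pop$bmi <- pop$weight_kg / (pop$height_cm / 100)^2
    check_grid(age_days_to_months(pop$age_days))

    if (config$record_ledgers) {
      led_intake[, day] <- intake
      led_tee[, day] <- tee
      led_pal[, day] <- pal
    }
    ledger <- data.frame(intake_kcal = intake, expenditure_kcal = tee,
                         calorie_gap_kcal = gap, pal = pal)
    summary_rows[[day]] <- summarize_day(pop, ledger, bundle, day = day)
  }

  pop$rmr_kcal <- schofield_rmr(pop$sex, pop$age_days / 365, pop$weight_kg,
                                pop$height_cm)
  if (floor_hits > 0L) {
    msg <- paste0(floor_hits, " agent-day(s) hit the ",
                  config$weight_floor_kg, " kg weight floor")
    warning(msg, call. = FALSE)
    log <- c(log, msg)
  }
  if (trunc_bouts > 0L) {
    msg <- paste0(trunc_bouts, " intervention bout(s) truncated for lack of ",
                  "sedentary minutes")
    warning(msg, call. = FALSE)
    log <- c(log, msg)
  }

  ledgers <- NULL
  if (config$record_ledgers) {
    ledgers <- data.frame(
      agent_id = rep(pop$id, n_days),
      day = rep(seq_len(n_days), each = n),
      intake_kcal = as.vector(led_intake),
      expenditure_kcal = as.vector(led_tee),
      calorie_gap_kcal = as.vector(led_intake - led_tee),
      pal = as.vector(led_pal)
    )
  }

  structure(list(
    config = config,
    bundle_profile = bundle$profile,
    summary = do.call(rbind, summary_rows),
    population = pop,
    population_init = pop_init,
    enrollments = enrollments,
    gap_total_kcal = gap_total,
    ledgers = ledgers,
    log = log
  ), class = "obesim_result")
}

#' @export
print.obesim_result <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  cat("<obesim_result> town", x$config$town_type, "|", x$config$n_agents,
      "agents |", x$config$n_days, "days | seed", x$config$seed, "\n")
  cat("  enabled:", if (length(x$config$enabled))
    paste(x$config$enabled, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  day %d: mean BMI %.2f | intake %.0f kcal | DEE %.0f kcal | surplus %.1f kcal\n",
              last$day, last$mean_bmi, last$mean_intake_kcal,
              last$mean_dee_kcal, last$mean_calorie_surplus_kcal))
  cat(sprintf("  overweight %%: M %.1f F %.1f | obese %%: M %.1f F %.1f\n",
              last$pct_overweight_male, last$pct_overweight_female,
              last$pct_obese_male, last$pct_obese_female))
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Writes `summary.csv` (the per-day series), `population_final.csv`,
#' `config_echo.json`, and `ledgers.csv` when ledgers were recorded.
#'
#' @param result An `obesim_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "obesim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(result$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write_population(result$population, file.path(dir, "population_final.csv"))
  cfg <- result$config
  cfg$specs <- NULL
  cfg$bundle <- if (is.character(result$config$bundle))
    result$config$bundle else result$bundle_profile
  jsonlite::write_json(unclass(cfg), file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$ledgers)) {
    write.csv(result$ledgers, file.path(dir, "ledgers.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Plot the daily monitor series of a run
#'
#' Four panels over simulation days: mean BMI, mean intake and daily energy
#' expenditure, mean calorie surplus, and weight-status percentages by sex.
#'
#' @param x An `obesim_result`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.obesim_result <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$day, s$mean_bmi, type = "l", xlab = "day",
                 ylab = "mean BMI (kg/m²)", main = "Mean BMI")
  graphics::matplot(s$day, cbind(s$mean_intake_kcal, s$mean_dee_kcal),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "day", ylab = "kcal/day",
                    main = "Intake (red) vs DEE (blue)")
  graphics::plot(s$day, s$mean_calorie_surplus_kcal, type = "l",
                 xlab = "day", ylab = "kcal/day", main = "Calorie surplus")
  graphics::abline(h = 0, lty = 3)
  graphics::matplot(s$day,
                    cbind(s$pct_obese_male, s$pct_obese_female,
                          s$pct_overweight_male, s$pct_overweight_female),
                    type = "l", lty = c(1, 1, 2, 2),
                    col = c("steelblue", "firebrick"),
                    xlab = "day", ylab = "%",
                    main = "Obese (solid) / overweight (dashed), M blue F red")
  invisible(x)
}
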