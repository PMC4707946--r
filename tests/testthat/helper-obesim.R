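# Shared fixtures, generated in code. The default bundle is cheap to build
# (362-row grid), so tests construct it directly.

default_bundle <- function(seed = 1L) generate_reference_bundle(seed = seed)

# A bundle with all randomness removed from intake: fixed multiplier equal to
# the town-A non-attendee baseline PAL, so intake == TEE for every agent.
equilibrium_bundle <- function(seed = 1L) {
  b <- generate_reference_bundle(seed = seed)
  pal0 <- obesim_baseline_pal_town_a(b)
  b$intake_multiplier_mean <- c(A = pal0, B = pal0, C = pal0 - 0.01)
  b$intake_multiplier_sd <- 0  # degenerate: every agent at the mean
  b
}

# Baseline non-attendee PAL for town A, from the bundle's pattern table
# (independent segment arithmetic, not the engine's code path).
obesim_baseline_pal_town_a <- function(b) {
  pat <- b$activity[b$activity$town_type == "A", ]
  val <- function(seg, len) {
    m <- pat$minutes[pat$segment == seg]
    met <- pat$met_level[pat$segment == seg]
    m * met + (len - m) * 1.5
  }
  (600 * 1.0 + val("home_morning", 60) + val("school", 420) +
     val("home_evening", 120) + 240 * 1.5) / 1440
}

one_agent <- function(bundle, attends = TRUE, sex = "male",
                      age_years = 8, seed = 99) {
  prof <- town_profile("A", bundle)
  pop <- create_population(1, prof, bundle, seed = seed,
                           afterschool_fraction = if (attends) 1 else 0)
  pop$sex <- sex
  pop$age_days <- as.integer(age_years * 365)
  pop$rmr_kcal <- schofield_rmr(pop$sex, age_years, pop$weight_kg,
                                pop$height_cm)
  pop
}

specs_full_coverage <- function(preset = "step4-text") {
  sp <- default_intervention_specs(preset)
  sp$reach <- 1
  sp$retention <- 1
  sp
}
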