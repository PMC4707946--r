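---
title: "Methods: an agent-based model of childhood BMI dynamics and school-based interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based model of childhood BMI dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesim)
```

## The model in one page

`obesim` simulates children aged 6–12 as individual agents over a 365-day
horizon. Each agent carries sex, age (in days), height, weight, a persistent
intake multiplier, and an after-school attendance flag. Every simulated day:

1. **Movement.** All agents are home until 08:00, at school 08:00–15:00,
   then either in the community (after-school program attendees, ~15%) or
   home until 19:00, and home thereafter. Every day of the run is a school
   day (see *Design choices*).
2. **Activity.** The day is realized at minute resolution: 600 minutes of
   sleep at MET 1.0, a town- and segment-specific activity bout in each
   awake segment, sedentary filler at MET 1.5 elsewhere. The time-weighted
   MET average over the 1,440 minutes is the physical activity level (PAL).
3. **Energy.** Resting metabolic rate comes from the age/sex-banded
   Schofield equations; expenditure is `TEE = RMR × PAL`; intake is
   `RMR × multiplier` plus any dietary intervention decrement, floored at
   zero.
4. **Settlement.** At midnight the calorie gap (intake − TEE) converts to
   weight at 7,700 kcal/kg; height grows by an age/sex-specific daily
   velocity, uncoupled from behavior; age advances one day; BMI is
   recomputed.

Population outcomes (mean BMI, intake, daily energy expenditure, calorie
surplus, and overweight/obesity percentages by sex, classified against the
85th/95th reference percentiles) are recorded daily.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| energy-balance constant | 7,700 | kcal/kg | converts calorie gap to weight change |
| intake multiplier (towns A, B) | mean 1.6, sd 0.1 | × RMR | daily intake; fixed per agent at init |
| intake multiplier (town C) | mean 1.59 | × RMR | exactly 0.01 below town A |
| sex ratio | 51.1% male | — | Bernoulli at init |
| after-school attendance | 0.15 | fraction | Bernoulli; gates community segment and out-of-school components |
| town B BMI median shift | +0.5 | kg/m² | relative to town A, at every age and sex |
| town A median offset | +1.0 | kg/m² | above the reference (pre-epidemic) median; `bmi_current_offset` |
| sleep | 600 min @ MET 1.0 | — | every day, every town |
| sedentary filler | MET 1.5 | — | all unassigned awake minutes |
| weight floor | 10 | kg | guard against nonphysical trajectories; crossing it warns |
| environment | 56 homes, 12 schools, 1 community | — | labels only; no spatial dynamics |

Intervention components (dose, reach, retention):

| component | dose | reach | retention |
|---|---|---|---|
| ASAP1 (before school) | 40 min @ 2.99 MET | 0.10 | 0.80 |
| ASAP2 (classroom) | 10 min @ 2.62 MET | 0.90 | 0.80 |
| ASAP3 (walk/run) | 30 min @ 4.96 MET | 0.75 | 0.90 |
| Drink Right | −60 kcal | 0.15 | 0.80 |
| Move More | 15 min @ 4.5 MET | 0.15 | 0.80 |
| Snack Smart | −68.25 kcal | 0.15 | 0.80 |

The two source descriptions of ASAP retention disagree (narrative: 80/80/90
for programs 1–3; tabulated: 80/90/80). The default preset `"step4-text"`
follows the narrative; `default_intervention_specs("table1")` follows the
table. Neither is silently preferred — the choice is a visible argument.

MVPA cutoff conventions (MET 6.0 for the school programs, 4.5 for
out-of-school reporting) are stored as reporting constants only; dynamics
depend on each bout's actual MET level.

## The synthetic reference bundle

The model's real-world inputs — growth-chart LMS tables, height velocities,
accelerometer-derived activity patterns, and an intake-on-RMR regression —
are not shipped. `generate_reference_bundle()` produces a synthetic bundle
with the same *structure* so the whole simulator is testable offline:

* **LMS table** on a monthly grid, ages 36–216 months, both sexes. Median
  BMI is a logistic curve in age (strictly increasing), the Box–Cox power
  `L` is negative (right-skewed BMI) and drifts slowly with age, and the
  coefficient of variation `S` grows from ~0.10 to ~0.13. The grid is wider
  than the 6–12 y initialization range so agents aging through a full year
  never exhaust it.
* **Height reference**: a saturating-exponential median-height curve whose
  per-day derivative is the growth velocity, so daily growth telescopes
  exactly onto the curve; initialization adds multiplicative normal noise
  (cv 0.042), drawn independently of the BMI z-score. Independence is the
  minimal assumption — the source material derives weight from height and
  BMI separately and states no joint correlation.
* **Activity patterns** per town and segment (elevated-MET minutes within
  the awake windows: morning 60 min, school 420, community 240, evening
  120). Defaults: 20 min @ 3.0 before school; 45 min @ 5.0 in school (towns
  A and C; town B has none — no physical education); 45 min @ 4.0 in the
  community (60 for town C, which has *more* after-school activity than A);
  90 min @ 3.5 in the evening. The town B/C after-school magnitudes are
  qualitative in the source ("some", "more than town A") and these
  quantifications are assumptions of this package.
* **Intake multipliers**: mean 1.6 (sd 0.1) for towns A and B, town C
  exactly 0.01 lower. The 1.6 mean is a conventional childhood
  physical-activity-level-scale value; the underlying survey regression
  coefficient is not published, so only the A→C offset is pinned.

These defaults put the baseline town-A PAL near 1.55 (non-attendees) to
1.62 (attendees), so an intake multiplier of 1.6 yields a modest mean
surplus (~50–60 kcal/day) and a visible upward BMI drift — the
"unnecessary weight gain" regime the interventions push against. Town B,
stripped of in-school activity, drifts considerably faster; town C starts
lower and eats slightly less. What passing tests show is therefore
*structural*: conservation, ordering, dose response, and every printed
parameter — not calibrated agreement with US surveillance data, which would
require the real reference inputs.

The town A median offset (+1.0 kg/m²) places the initial town-A obese
fraction near 15% under these synthetic curves, matching the stylized
"average US community" framing; it is configurable.

## Numerical and procedural choices

* **Schofield band boundary.** The printed bands ("3 to 10", "10 to 18")
  overlap at exactly 10; age 10 is assigned to the older band. The bands
  are discontinuous there and are applied verbatim — no smoothing.
* **Age lookup.** Ages are converted to months (`floor(days/365 × 12)`) and
  snapped to the nearest grid record, ties to the younger age.
  Interpolation between records is deliberately not done; the source's
  practice is unstated, and nearest-age lookup keeps the transform exactly
  invertible at grid ages.
* **LMS domain.** Initialization z-scores are redrawn while
  `1 + L·S·z ≤ 0` (with `L < 0` this truncates the extreme upper tail at
  z ≈ 4.5; probability mass ~3×10⁻⁶).
* **Bout placement.** Baseline bouts sit at segment starts; intervention
  bouts then *replace* sedentary minutes (never sleep, never baseline
  activity) in their window — replacement is the only reading that keeps
  the day at exactly 1,440 minutes. Program 1 runs in the 07:00–08:00
  pre-school hour; programs 2–3 within school hours; Move More in community
  hours. A bout exceeding the segment's sedentary budget is truncated with
  a warning.
* **Dropout timing.** Retention is defined only as end-of-year survival; a
  dropout day uniform over days 1–365 is assumed for the (1 − retention)
  flagged agents, the smoothest assumption consistent with the definition.
  An agent active on day *d* is active on every earlier day.
* **Eligibility.** Out-of-school components enroll only after-school
  attendees, with reach applied *within* that eligible set (the alternative
  reading — that the 15% reach is the attendee fraction itself — would make
  reach redundant with attendance). By default each school runs at most one
  enabled in-school program (`asap_exclusive = TRUE`); dietary decrements
  apply only on days the agent attends the community segment.
* **RNG streams.** All randomness derives from the run seed with a fixed
  order: population first, school-program assignment second, per-component
  enrollment third. The population stream is seeded independently, so
  toggling interventions never perturbs the drawn children — on/off
  comparisons under one seed are exactly paired. Runs are bit-reproducible.
* **Settlement order.** Energy is settled once per day at midnight (hourly
  tick records sum exactly to the daily ledger); the weight floor (10 kg)
  is applied after the update, with a logged warning, never silently.

## Design choices where the source was contradictory or silent

* "1 community" versus "3 community locations": both appear; the default is
  1 (`n_communities` exists as a knob). The count is a label with no
  dynamic effect.
* Every day is a school day: an academic calendar and weekday/weekend
  behavioral differences are explicitly listed as future refinements of the
  base model, so the base model uses the simple 365-day calendar.
* "51% boys" versus "51.1% boys": the more precise tabulated value is used.
* Population size is decoupled from the 12-school count (the "400 students
  per school" figure would pin n; it is not enforced).

## What the test suite runs

Unit and property tests run at small n (tens to hundreds of agents). The
heavier checks use: a 1,000-agent × 365-day run for the mass-conservation
audit (closure to 10⁻⁶ kg); 5,000 agents × 365 days per town for the final
obesity-prevalence ordering C < A < B; and 1,500 agents × 365 days for the
seven paired runs (baseline + six single components at full coverage)
verifying that every component weakly — and every activity component
strictly — lowers mean final BMI. Composition checks (sex ratio,
attendance, reach) use n = 10,000 against 3-standard-error binomial bands.

## Known limitations

* No behavioral feedback: intake multipliers are fixed at initialization;
  no habit formation, spillover, or household contagion (none is specified
  in the source model).
* No body-composition partitioning or adaptive thermogenesis; the single
  7,700 kcal/kg constant applies at all ages and both signs of the gap.
* Race/ethnicity and socioeconomic status are qualitative town labels that
  drive no equation and are not carried on agents.
* The synthetic bundle is shaped like, but numerically distinct from, real
  growth references; absolute prevalence levels are illustrative until a
  real bundle is supplied.
* With the default multiplier spread (sd 0.1), a few agents in the extreme
  low-intake tail of long runs can reach the 10 kg weight floor; these
  agent-days are counted and logged in the run warnings.
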