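## Intervention components: three in-school physical-activity programs
## (ASAP1-3) and three out-of-school-time components (Drink Right, Move More,
## Snack Smart), each with dose, reach and retention, plus stochastic
## enrollment and dropout.

COMPONENTS <- c("ASAP1", "ASAP2", "ASAP3", "DrinkRight", "MoveMore",
                "SnackSmart")

#' Default intervention specifications
#'
#' Returns the six modeled components with their doses, reach and retention:
#' \itemize{
#'   \item ASAP1 (before-school): 40 min @ 2.99 MET, reach 10\%
#'   \item ASAP2 (classroom): 10 min @ 2.62 MET, reach 90\%
#'   \item ASAP3 (walk/run): 30 min @ 4.96 MET, reach 75\%
#'   \item Drink Right: -60 kcal; Move More: 15 min @ 4.5 MET;
#'     Snack Smart: -68.25 kcal (all reach 15\%, retention 80\%, restricted
#'     to after-school attendees)
#' }
#' The two source descriptions of ASAP retention disagree; `preset
#' = "step4-text"` (default) uses 80/80/90\% for programs 1-3, `preset =
#' "table1"` uses 80/90/80\%.
#'
#' @param preset `"step4-text"` (default) or `"table1"`.
#' @return A data frame with one row per component: `component_id`, `type`
#'   (`"activity"` or `"dietary"`), `dose_minutes`, `dose_met`, `dose_kcal`,
#'   `reach`, `retention`, `eligible_context`, `window` (the day segment an
#'   activity bout is placed in).
#' @export
default_intervention_specs <- function(preset = c("step4-text", "table1")) {
  preset <- match.arg(preset)
  asap_retention <- if (preset == "step4-text") c(0.80, 0.80, 0.90)
                    else c(0.80, 0.90, 0.80)
  specs <- data.frame(
    component_id = COMPONENTS,
    type = c("activity", "activity", "activity",
             "dietary", "activity", "dietary"),
    dose_minutes = c(40, 10, 30, NA, 15, NA),
    dose_met = c(2.99, 2.62, 4.96, NA, 4.5, NA),
    dose_kcal = c(NA, NA, NA, -60, NA, -68.25),
    reach = c(0.10, 0.90, 0.75, 0.15, 0.15, 0.15),
    retention = c(asap_retention, 0.80, 0.80, 0.80),
    eligible_context = c("school", "school", "school",
                         "community", "community", "community"),
    window = c("home_morning", "school", "school", NA, "community", NA),
    stringsAsFactors = FALSE
  )
  rownames(specs) <- specs$component_id
  specs
}

#' Assign stochastic enrollment and dropout for one component
#'
#' Each eligible agent enrolls with probability `reach`. Each enrolled agent
#' is independently flagged for dropout with probability `1 - retention`;
#' flagged agents receive a dropout day uniform over 1-365. Eligibility
#' defaults to the component's context: school components are open to all
#' students, community components only to after-school attendees.
#'
#' @param agents An `obesim_population`.
#' @param spec A single row of [default_intervention_specs()].
#' @param seed Integer seed.
#' @param eligible Optional logical vector overriding the default eligibility
#'   (e.g. to restrict a school program to the schools that run it).
#' @return A data frame: `agent_id`, `component_id`, `enrolled`,
#'   `dropout_day` (`NA` for agents who stay the full year). An agent is
#'   active on day `d` iff enrolled and (`dropout_day` is `NA` or
#'   `d < dropout_day`).
#' @export
assign_enrollment <- function(agents, spec, seed, eligible = NULL) {
  stopifnot(nrow(spec) == 1L)
  n <- nrow(agents)
  if (is.null(eligible)) {
    eligible <- if (spec$eligible_context == "community") {
      agents$attends_afterschool
    } else {
      rep(TRUE, n)
    }
  }
  stopifnot(length(eligible) == n)
  set.seed(as.integer(seed))
  enrolled <- eligible & runif(n) < spec$reach
  dropout_day <- rep(NA_integer_, n)
  flagged <- enrolled & runif(n) < (1 - spec$retention)
  if (any(flagged)) {
    dropout_day[flagged] <- sample.int(DAYS_PER_YEAR, sum(flagged),
                                       replace = TRUE)
  }
  data.frame(agent_id = agents$id,
             component_id = spec$component_id,
             enrolled = enrolled,
             dropout_day = dropout_day,
             stringsAsFactors = FALSE)
}

#' Is an enrollment active on a given day?
#'
#' @param enrollment A data frame from [assign_enrollment()].
#' @param day Simulation day (1-based).
#' @return Logical vector, one per row of `enrollment`.
#' @export
enrollment_active <- function(enrollment, day) {
  enrollment$enrolled &
    (is.na(enrollment$dropout_day) | day < enrollment$dropout_day)
}

#' Total dietary kcal adjustment for one agent-day
#'
#' Sums the kcal doses of the agent's active dietary components. Dietary
#' doses apply only on days the agent attends the community (after-school)
#' segment; non-attendees receive 0.
#'
#' @param specs Intervention spec data frame.
#' @param active_components Character vector of component ids active for the
#'   agent on this day.
#' @param attends Does the agent attend the after-school program today?
#' @return kcal adjustment (<= 0).
#' @export
apply_dietary_dose <- function(specs, active_components, attends) {
  if (!attends || length(active_components) == 0L) return(0)
  rows <- specs[specs$component_id %in% active_components &
                  specs$type == "dietary", , drop = FALSE]
  if (nrow(rows) == 0L) return(0)
  sum(rows$dose_kcal)
}
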