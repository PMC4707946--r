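## Daily schedule: agent movement between home, school and community, and the
## minute-resolution MET timeline for one day.
##
## Clock layout (minutes from midnight, half-open intervals):
##   [0, 420)     sleep (home)            420 min @ MET 1.0
##   [420, 480)   home morning, awake      60 min
##   [480, 900)   school                  420 min   (08:00-15:00)
##   [900, 1140)  community or home       240 min   (15:00-19:00)
##   [1140, 1260) home evening, awake     120 min
##   [1260, 1440) sleep (home)            180 min @ MET 1.0
## Sleep totals 600 minutes ("10 hours per night"). Within each awake segment
## the town's baseline activity bout is placed at the segment start; the
## remainder is sedentary filler at MET 1.5. Intervention bouts replace
## sedentary minutes, never sleep or baseline activity.

SEGMENT_WINDOWS <- list(
  home_morning = 421:480,    # 1-based minute indices (minute 0 = index 1)
  school       = 481:900,
  community    = 901:1140,
  home_evening = 1141:1260
)
SLEEP_IDX <- c(1:420, 1261:1440)

#' Context an agent occupies at a given hour
#'
#' All agents are home before 08:00, at school 08:00-15:00, and home from
#' 19:00. Between 15:00 and 19:00, after-school attendees are in the
#' community; everyone else is home.
#'
#' @param agent Agent row(s) with an `attends_afterschool` column.
#' @param hour Hour of day, 0-23.
#' @return Character vector: `"home"`, `"school"` or `"community"`.
#' @export
context_at <- function(agent, hour) {
  if (any(hour < 0 | hour > 23)) stop("hour must be 0-23", call. = FALSE)
  n <- max(nrow(agent), length(hour))
  attends <- rep_len(agent$attends_afterschool, n)
  hour <- rep_len(hour, n)
  ifelse(hour < 8, "home",
         ifelse(hour < 15, "school",
                ifelse(hour < 19, ifelse(attends, "community", "home"),
                       "home")))
}

#' Build one agent's minute-resolution day timeline
#'
#' Lays down the town's baseline activity pattern (sleep 600 min at MET 1.0,
#' baseline bouts per awake segment, sedentary filler at MET 1.5) and then
#' inserts the agent's active intervention bouts, each replacing sedentary
#' minutes within its program window. A bout that exceeds the available
#' sedentary minutes in its segment is truncated with a warning.
#'
#' @param agent A single agent row (`attends_afterschool` is honored: the
#'   community pattern and community-window bouts apply only to attendees).
#' @param profile A `town_profile`.
#' @param bundle A `reference_bundle`.
#' @param interventions `NULL`, or a data frame of intervention specs (rows of
#'   [default_intervention_specs()]) that are *active* for this agent today;
#'   only activity components (non-`NA` `dose_minutes`) alter the timeline.
#' @return A data frame with 1440 rows: `minute` (0-1439), `context`, `met`.
#' @export
build_day_timeline <- function(agent, profile, bundle, interventions = NULL) {
  stopifnot(nrow(agent) == 1L, inherits(profile, "town_profile"))
  attends <- isTRUE(agent$attends_afterschool)

  met <- rep(MET_SEDENTARY, 1440)
  met[SLEEP_IDX] <- MET_SLEEP
  context <- rep("home", 1440)
  context[SEGMENT_WINDOWS$school] <- "school"
  if (attends) context[SEGMENT_WINDOWS$community] <- "community"

  pat <- activity_pattern(bundle, profile$town_type)
  for (seg in names(SEGMENT_WINDOWS)) {
    if (seg == "community" && !attends) next
    p <- pat[[seg]]
    if (is.null(p) || p$minutes[1] == 0) next
    w <- SEGMENT_WINDOWS[[seg]]
    met[w[seq_len(p$minutes[1])]] <- p$met_level[1]
  }

  if (!is.null(interventions) && nrow(interventions)) {
    act <- interventions[!is.na(interventions$dose_minutes), , drop = FALSE]
    for (k in seq_len(nrow(act))) {
      seg <- act$window[k]
      if (seg == "community" && !attends) next
      w <- SEGMENT_WINDOWS[[seg]]
      sed <- w[met[w] == MET_SEDENTARY]
      take <- min(act$dose_minutes[k], length(sed))
      if (take < act$dose_minutes[k]) {
        warning("bout for ", act$component_id[k], " truncated from ",
                act$dose_minutes[k], " to ", take, " minutes (segment ",
                seg, " sedentary time exhausted)", call. = FALSE)
      }
      if (take > 0) met[sed[seq_len(take)]] <- act$dose_met[k]
    }
  }

  data.frame(minute = 0:1439, context = context, met = met)
}

#' Aggregate a day timeline into hourly MET-minutes
#'
#' Hourly "tick" records; they sum exactly to the day's total MET-minutes
#' (1440 x PAL).
#'
#' @param timeline A timeline from [build_day_timeline()].
#' @return Numeric vector of length 24, MET-minutes per hour.
#' @export
met_minutes_by_hour <- function(timeline) {
  as.numeric(tapply(timeline$met, timeline$minute %/% 60, sum))
}

## Vectorized segment accounting used by the engine ---------------------------

# Per-segment sedentary filler available after the baseline bout, for one
# town. Community applies to attendees only.
segment_sedentary <- function(pat) {
  lens <- c(home_morning = 60, school = 420, community = 240,
            home_evening = 120)
  vapply(names(lens), function(seg) {
    p <- pat[[seg]]
    lens[[seg]] - if (is.null(p)) 0 else p$minutes[1]
  }, numeric(1))
}

# Baseline daily MET-minutes for one town, for attendees / non-attendees.
# Non-attendees spend the community window at home, fully sedentary.
baseline_met_minutes <- function(pat) {
  awake <- function(seg, len) {
    p <- pat[[seg]]
    if (is.null(p)) return(len * MET_SEDENTARY)
    p$minutes[1] * p$met_level[1] + (len - p$minutes[1]) * MET_SEDENTARY
  }
  common <- SLEEP_MINUTES * MET_SLEEP +
    awake("home_morning", 60) + awake("school", 420) +
    awake("home_evening", 120)
  c(non_attendee = common + 240 * MET_SEDENTARY,
    attendee = common + awake("community", 240))
}
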