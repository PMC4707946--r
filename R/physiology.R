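## Energy-balance physiology: Schofield RMR, PAL, TEE, intake, the
## 7,700 kcal/kg weight update, and daily height growth.

#' Schofield resting metabolic rate for children
#'
#' Age- and sex-banded linear equations in weight `W` (kg) and height `H`
#' (cm), returning kcal/day:
#' \itemize{
#'   \item boys 3-10 y: `19.59 W + 1.303 H + 414.9`
#'   \item boys 10-18 y: `16.25 W + 1.372 H + 515.5`
#'   \item girls 3-10 y: `16.969 W + 1.618 H + 371.2`
#'   \item girls 10-18 y: `8.365 W + 4.65 H + 200.0`
#' }
#' The bands meet at age 10; exact age 10 is assigned to the older band. The
#' two bands are not continuous at the boundary and no smoothing is applied.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in years; must lie in \[3, 18).
#' @param weight_kg Weight in kg (>= 0).
#' @param height_cm Height in cm (>= 0).
#' @return RMR in kcal/day. All arguments are recycled to a common length.
#' @examples
#' schofield_rmr("male", 8, 30, 130)   # 19.59*30 + 1.303*130 + 414.9
#' @export
schofield_rmr <- function(sex, age_years, weight_kg, height_cm) {
  n <- max(length(sex), length(age_years), length(weight_kg),
           length(height_cm))
  sex <- rep_len(sex, n)
  age_years <- rep_len(age_years, n)
  W <- rep_len(weight_kg, n)
  H <- rep_len(height_cm, n)
  if (any(age_years < 3 | age_years >= 18)) {
    stop("age ", age_years[which(age_years < 3 | age_years >= 18)[1]],
         " outside the supported range [3, 18) years", call. = FALSE)
  }
  if (any(W < 0) || any(H < 0)) {
    stop("weight and height must be non-negative", call. = FALSE)
  }
  if (!all(sex %in% SEXES)) stop("sex must be male or female", call. = FALSE)
  male <- sex == "male"
  young <- age_years < 10
  rmr <- numeric(n)
  i <- male & young
  rmr[i] <- 19.59 * W[i] + 1.303 * H[i] + 414.9
  i <- male & !young
  rmr[i] <- 16.25 * W[i] + 1.372 * H[i] + 515.5
  i <- !male & young
  rmr[i] <- 16.969 * W[i] + 1.618 * H[i] + 371.2
  i <- !male & !young
  rmr[i] <- 8.365 * W[i] + 4.65 * H[i] + 200.0
  rmr
}

#' Time-weighted physical activity level from a minute-resolution day
#'
#' @param mets Numeric vector of length 1440: the MET level assigned to each
#'   minute of the day. All values must be >= 1.
#' @return The PAL: `sum(mets) / 1440`.
#' @export
compute_pal <- function(mets) {
  if (length(mets) != 1440L) {
    stop("MET assignment must cover exactly 1440 minutes (got ",
         length(mets), ")", call. = FALSE)
  }
  if (any(mets < 1)) stop("MET levels must be >= 1.0", call. = FALSE)
  sum(mets) / 1440
}

#' Total energy expenditure
#'
#' @param rmr Resting metabolic rate, kcal/day (> 0).
#' @param pal Physical activity level (>= 1).
#' @return `rmr * pal`, kcal/day.
#' @export
total_energy_expenditure <- function(rmr, pal) {
  if (any(rmr <= 0)) stop("rmr must be positive", call. = FALSE)
  if (any(pal < 1)) stop("pal must be >= 1", call. = FALSE)
  rmr * pal
}

#' Daily caloric intake
#'
#' Intake is a fixed per-agent multiple of RMR plus any intervention
#' adjustment (a kcal decrement for dietary components), floored at zero.
#'
#' @param rmr RMR in kcal/day (> 0).
#' @param multiplier Intake multiplier (> 0).
#' @param kcal_adjustment Additive adjustment in kcal (default 0; dietary
#'   intervention doses are negative).
#' @return Intake in kcal/day, never negative.
#' @export
daily_intake <- function(rmr, multiplier, kcal_adjustment = 0) {
  if (any(rmr <= 0)) stop("rmr must be positive", call. = FALSE)
  if (any(multiplier <= 0)) stop("multiplier must be positive", call. = FALSE)
  pmax(0, rmr * multiplier + kcal_adjustment)
}

#' Convert a daily calorie gap into weight change
#'
#' Weight changes at [KCAL_PER_KG] (7,700 kcal per kg). A configurable floor
#' guards against nonphysical trajectories; crossing it raises a warning,
#' never silently.
#'
#' @param weight_kg Current weight in kg (> 0).
#' @param calorie_gap_kcal Intake minus expenditure, kcal.
#' @param min_weight_kg Weight floor in kg (default 10).
#' @return Updated weight in kg.
#' @examples
#' apply_energy_balance(30, 7700)   # 31
#' @export
apply_energy_balance <- function(weight_kg, calorie_gap_kcal,
                                 min_weight_kg = 10) {
  if (any(weight_kg <= 0)) stop("weight must be positive", call. = FALSE)
  new_w <- weight_kg + calorie_gap_kcal / KCAL_PER_KG
  if (any(new_w < min_weight_kg)) {
    warning(sum(new_w < min_weight_kg), " agent-day(s) hit the ",
            min_weight_kg, " kg weight floor", call. = FALSE)
    new_w <- pmax(new_w, min_weight_kg)
  }
  new_w
}

#' Advance an agent by one day of height growth
#'
#' Adds one day's height velocity (from the bundle, by age and sex) to the
#' agent's height, increments age by one day, and recomputes BMI and RMR.
#' Growth is uncoupled from behavior: weight is untouched.
#'
#' @param agent One or more rows of an `obesim_population`.
#' @param bundle A `reference_bundle`.
#' @return The updated agent row(s).
#' @export
grow_height <- function(agent, bundle) {
  g <- lookup_growth(bundle, age_days_to_months(agent$age_days), agent$sex)
  agent$height_cm <- agent$height_cm + g$height_velocity
  agent$age_days <- agent$age_days + 1L
  agent$bmi <- agent$weight_kg / (agent$height_cm / 100)^2
  agent$rmr_kcal <- schofield_rmr(agent$sex, agent$age_days / 365,
                                  agent$weight_kg, agent$height_cm)
  agent
}
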