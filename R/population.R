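## Population initialization: LMS quantile/z-score transforms, town profiles,
## agent generation, weight-status classification, snapshot I/O.

#' LMS quantile transform: standard-normal deviate to measurement
#'
#' Maps a standard-normal deviate `z` to the skew-normal measurement scale of
#' an LMS growth reference: `M * (1 + L*S*z)^(1/L)` for `L != 0` and
#' `M * exp(S*z)` for `L = 0`.
#'
#' @param L Box-Cox power (dimensionless).
#' @param M Median of the measurement (e.g. kg/m^2 for BMI); must be > 0.
#' @param S Coefficient of variation; must be > 0.
#' @param z Standard-normal deviate(s). For `L != 0`, `1 + L*S*z` must be
#'   positive or an error is raised.
#' @return Measurement value(s) on the reference scale.
#' @examples
#' lms_quantile(-1.8, 16.5, 0.11, 0)      # the median
#' lms_quantile(-1.8, 16.5, 0.11, 1.645)  # ~95th percentile
#' @export
lms_quantile <- function(L, M, S, z) {
  n <- max(length(L), length(M), length(S), length(z))
  L <- rep_len(L, n); M <- rep_len(M, n)
  S <- rep_len(S, n); z <- rep_len(z, n)
  if (any(M <= 0)) stop("LMS median M must be positive", call. = FALSE)
  if (any(S <= 0)) stop("LMS coefficient S must be positive", call. = FALSE)
  base <- 1 + L * S * z
  nz <- L != 0
  if (any(nz & base <= 0)) {
    stop("z outside the valid range for the given L and S ",
         "(1 + L*S*z must be positive)", call. = FALSE)
  }
  out <- numeric(n)
  out[nz] <- M[nz] * base[nz]^(1 / L[nz])
  out[!nz] <- M[!nz] * exp(S[!nz] * z[!nz])
  out
}

#' LMS z-score: measurement to standard-normal deviate
#'
#' Inverse of [lms_quantile()]: `((x/M)^L - 1) / (L*S)` for `L != 0`,
#' `log(x/M) / S` for `L = 0`.
#'
#' @param x Measurement value(s), > 0.
#' @inheritParams lms_quantile
#' @return Standard-normal deviate(s).
#' @export
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(x <= 0)) stop("measurement must be positive", call. = FALSE)
  if (any(M <= 0) || any(S <= 0)) {
    stop("LMS M and S must be positive", call. = FALSE)
  }
  out <- numeric(n)
  nz <- L != 0
  out[nz] <- ((x[nz] / M[nz])^L[nz] - 1) / (L[nz] * S[nz])
  out[!nz] <- log(x[!nz] / M[!nz]) / S[!nz]
  out
}

#' Build a town profile
#'
#' Encodes how a stylized town type shifts the BMI reference: town C uses the
#' bundle's reference ("pre-epidemic") median directly, town A adds a
#' current-population offset, town B sits exactly 0.5 kg/m^2 above town A.
#' The town's intake-multiplier parameters are copied from the bundle.
#'
#' @param town_type `"A"`, `"B"` or `"C"`.
#' @param bundle A `reference_bundle`.
#' @param bmi_current_offset kg/m^2 added to the reference median for town A
#'   (and, plus 0.5, for town B). Default 1.0.
#' @return An object of class `town_profile`.
#' @export
town_profile <- function(town_type = c("A", "B", "C"), bundle,
                         bmi_current_offset = 1.0) {
  town_type <- match.arg(town_type)
  offset <- switch(town_type,
                   A = bmi_current_offset,
                   B = bmi_current_offset + 0.5,
                   C = 0)
  structure(list(
    town_type = town_type,
    bmi_median_offset = offset,
    intake_multiplier_mean = unname(bundle$intake_multiplier_mean[[town_type]]),
    intake_multiplier_sd = bundle$intake_multiplier_sd
  ), class = "town_profile")
}

age_days_to_months <- function(age_days) as.integer(floor(age_days / 365 * 12))

# Standard-normal draws restricted to the LMS domain (1 + L*S*z > 0).
draw_valid_z <- function(n, L, S) {
  z <- rnorm(n)
  repeat {
    bad <- L != 0 & (1 + L * S * z) <= 0
    if (!any(bad)) break
    z[bad] <- rnorm(sum(bad))
  }
  z
}

#' Generate an agent population for a town
#'
#' Draws `n` simulated children: sex Bernoulli(0.511 male), age continuous
#' uniform over 6-13 years (in days), height from the bundle's median
#' height-for-age with multiplicative normal noise, BMI via the LMS transform
#' with the town-shifted median, weight derived from BMI and height, a
#' persistent intake multiplier (normal, truncated positive), an after-school
#' attendance flag, and random home/school assignments. Height and BMI are
#' drawn independently. Deterministic for a fixed seed.
#'
#' @param n Number of agents (>= 1).
#' @param profile A `town_profile`.
#' @param bundle A `reference_bundle`.
#' @param seed Integer seed.
#' @param afterschool_fraction Probability an agent attends the after-school
#'   community program (default 0.15).
#' @param n_homes,n_schools Environment sizes (defaults 56 and 12).
#' @return A data frame of class `obesim_population`, one row per agent, with
#'   columns `id`, `sex`, `age_days`, `height_cm`, `weight_kg`, `bmi`,
#'   `rmr_kcal`, `intake_multiplier`, `attends_afterschool`, `home_id`,
#'   `school_id`.
#' @export
create_population <- function(n, profile, bundle, seed,
                              afterschool_fraction = 0.15,
                              n_homes = 56L, n_schools = 12L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("population size n must be >= 1", call. = FALSE)
  }
  stopifnot(inherits(profile, "town_profile"),
            inherits(bundle, "reference_bundle"),
            afterschool_fraction >= 0, afterschool_fraction <= 1,
            n_homes >= 1, n_schools >= 1)
  n <- as.integer(n)
  set.seed(as.integer(seed))

  # Draw order (fixed): sex, age, height noise, BMI z, intake multiplier,
  # after-school flag, home, school.
  sex <- ifelse(runif(n) < 0.511, "male", "female")
  age_days <- as.integer(floor(runif(n, 6 * 365, 13 * 365)))
  months <- age_days_to_months(age_days)

  g <- lookup_growth(bundle, months, sex)
  height_cm <- g$height_median_cm * (1 + g$height_cv * rnorm(n))

  rec <- lookup_lms(bundle, months, sex)
  z <- draw_valid_z(n, rec$L, rec$S)
  bmi <- lms_quantile(rec$L, rec$M + profile$bmi_median_offset, rec$S, z)
  weight_kg <- bmi * (height_cm / 100)^2

  mult <- rnorm(n, profile$intake_multiplier_mean, profile$intake_multiplier_sd)
  while (any(mult <= 0)) {
    mult[mult <= 0] <- rnorm(sum(mult <= 0), profile$intake_multiplier_mean,
                             profile$intake_multiplier_sd)
  }
  attends <- runif(n) < afterschool_fraction
  home_id <- sample.int(n_homes, n, replace = TRUE)
  school_id <- sample.int(n_schools, n, replace = TRUE)

  pop <- data.frame(
    id = seq_len(n),
    sex = sex,
    age_days = age_days,
    height_cm = height_cm,
    weight_kg = weight_kg,
    bmi = bmi,
    rmr_kcal = schofield_rmr(sex, age_days / 365, weight_kg, height_cm),
    intake_multiplier = mult,
    attends_afterschool = attends,
    home_id = home_id,
    school_id = school_id
  )
  class(pop) <- c("obesim_population", "data.frame")
  pop
}

#' Classify weight status against the reference distribution
#'
#' Inverts the LMS transform against the bundle's (town-unshifted) reference
#' record for each agent's age and sex, converts the z-score to a percentile,
#' and applies the pediatric convention: obese at or above the 95th
#' percentile, overweight at or above the 85th.
#'
#' @param population An `obesim_population` (or any data frame with `sex`,
#'   `age_days`, `bmi` columns).
#' @param bundle A `reference_bundle`.
#' @return A factor with levels `normal`, `overweight`, `obese`.
#' @export
classify_weight_status <- function(population, bundle) {
  months <- age_days_to_months(population$age_days)
  rec <- lookup_lms(bundle, months, population$sex)
  z <- lms_zscore(population$bmi, rec$L, rec$M, rec$S)
  p <- pnorm(z)
  factor(ifelse(p >= 0.95, "obese", ifelse(p >= 0.85, "overweight", "normal")),
         levels = c("normal", "overweight", "obese"))
}

#' Write a population snapshot to CSV
#'
#' One row per agent; restored by [read_population()].
#' @param population An `obesim_population`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' Read a population snapshot written by [write_population()]
#' @param path CSV path.
#' @return An `obesim_population` data frame.
#' @export
read_population <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  class(pop) <- c("obesim_population", "data.frame")
  pop
}

#' @export
print.obesim_population <- function(x, ...) {
  cat("<obesim_population> n =", nrow(x),
      sprintf("(%.1f%% male, %.1f%% after-school)",
              100 * mean(x$sex == "male"),
              100 * mean(x$attends_afterschool)), "\n")
  print(head(as.data.frame(x)), ...)
  invisible(x)
}
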