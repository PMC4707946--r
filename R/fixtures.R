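## Synthetic reference bundles: growth-chart-shaped LMS tables, height
## velocities, and town activity patterns. These emulate the *structure* of
## public growth-chart / survey inputs with smooth synthetic curves; a user
## can supply a real bundle in the same JSON format.

BUNDLE_VERSION <- "1.0"

#' Generate a synthetic reference bundle
#'
#' Builds the full reference-data bundle the simulator needs: an LMS table
#' (Box-Cox power `L`, median BMI `M`, coefficient of variation `S`) on a
#' monthly age grid for both sexes, median height and height growth velocity
#' by age and sex, per-town activity patterns (MET level and minutes by time
#' segment), and intake-multiplier parameters per town type.
#'
#' The `"default"` profile uses smooth logistic-shaped median curves over ages
#' 3-18 y (36-216 months), so `M` is strictly increasing in age within sex.
#' Town C's intake-multiplier mean is exactly 0.01 below town A's. The default
#' profile is fully deterministic; `seed` is recorded in the bundle and
#' reserved for stochastic profiles.
#'
#' @param seed Integer seed, recorded in the bundle.
#' @param profile Name of a built-in profile; only `"default"` is defined.
#' @return An object of class `reference_bundle`: a list with elements
#'   `version`, `profile`, `seed`, `lms`, `growth`, `activity` (data frames),
#'   `intake_multiplier_mean` (named numeric, towns A/B/C) and
#'   `intake_multiplier_sd`.
#' @examples
#' b <- generate_reference_bundle(seed = 1)
#' head(b$lms)
#' b$intake_multiplier_mean
#' @export
generate_reference_bundle <- function(seed = 1L, profile = "default") {
  if (!is.character(profile) || length(profile) != 1L || profile != "default") {
    stop("unknown reference profile: ", paste(profile, collapse = ", "),
         " (available: \"default\")", call. = FALSE)
  }
  ages <- 36:216  # months, ages 3-18 y
  grid <- expand.grid(age_months = as.integer(ages), sex = SEXES,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ay <- grid$age_months / 12
  male <- grid$sex == "male"

  # Median BMI: logistic in age, strictly increasing; sexes differ slightly.
  M <- ifelse(male,
              14.2 + 8.0 * plogis((ay - 12.5) / 3.2),
              14.0 + 8.6 * plogis((ay - 12.2) / 3.0))
  # Box-Cox power and CV drift slowly with age (left-skewed BMI throughout).
  L <- -2.2 + 0.035 * (ay - 3)
  S <- 0.095 + 0.0028 * (ay - 3)
  lms <- data.frame(grid, L = L, M = M, S = S)

  # Median height: saturating-exponential growth; velocity is its exact
  # per-day derivative so cumulative daily growth telescopes to the curve.
  h_med <- ifelse(male, 172 - 122 * exp(-ay / 7.5), 163 - 113 * exp(-ay / 7.2))
  h_vel <- ifelse(male, (122 / 7.5) * exp(-ay / 7.5),
                  (113 / 7.2) * exp(-ay / 7.2)) / 365
  growth <- data.frame(grid, height_velocity = h_vel,
                       height_median_cm = h_med, height_cv = 0.042)

  activity <- default_activity_patterns()

  structure(list(
    version = BUNDLE_VERSION,
    profile = profile,
    seed = as.integer(seed),
    lms = lms,
    growth = growth,
    activity = activity,
    intake_multiplier_mean = c(A = 1.6, B = 1.6, C = 1.6 - 0.01),
    intake_multiplier_sd = 0.1
  ), class = "reference_bundle")
}

# Per-town baseline activity: minutes at an elevated MET within each awake
# segment; the remainder of the segment is sedentary filler at MET 1.5.
# Town B has no in-school PE; town C has more after-school activity than A.
default_activity_patterns <- function() {
  pat <- rbind(
    data.frame(town_type = "A",
               segment = c("home_morning", "school", "community",
                           "home_evening", "sleep"),
               met_level = c(3.0, 5.0, 4.0, 3.5, 1.0),
               minutes = c(20, 45, 45, 90, 600)),
    data.frame(town_type = "B",
               segment = c("home_morning", "school", "community",
                           "home_evening", "sleep"),
               met_level = c(3.0, 5.0, 4.0, 3.5, 1.0),
               minutes = c(20, 0, 45, 90, 600)),
    data.frame(town_type = "C",
               segment = c("home_morning", "school", "community",
                           "home_evening", "sleep"),
               met_level = c(3.0, 5.0, 4.0, 3.5, 1.0),
               minutes = c(20, 45, 60, 90, 600))
  )
  pat
}

validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  with(bundle, {
    if (any(lms$M <= 0) || any(lms$S <= 0)) {
      stop("invalid bundle: LMS M and S must be positive", call. = FALSE)
    }
    for (sx in SEXES) {
      sub <- lms[lms$sex == sx, ]
      sub <- sub[order(sub$age_months), ]
      if (any(diff(sub$age_months) != diff(range(sub$age_months)) /
              (nrow(sub) - 1))) {
        stop("invalid bundle: LMS age grid has gaps for sex ", sx,
             call. = FALSE)
      }
    }
    if (!setequal(names(intake_multiplier_mean), TOWN_TYPES)) {
      stop("invalid bundle: intake_multiplier_mean must name towns A, B, C",
           call. = FALSE)
    }
    off <- intake_multiplier_mean[["A"]] - intake_multiplier_mean[["C"]]
    if (abs(off - 0.01) > 1e-12) {
      stop("invalid bundle: town C intake multiplier must sit exactly 0.01 ",
           "below town A (found offset ", off, ")", call. = FALSE)
    }
    slp <- activity[activity$segment == "sleep", ]
    if (any(slp$met_level != MET_SLEEP) || any(slp$minutes != SLEEP_MINUTES)) {
      stop("invalid bundle: sleep segment must be 600 minutes at MET 1.0",
           call. = FALSE)
    }
    if (any(activity$met_level < 1.0)) {
      stop("invalid bundle: MET levels must be >= 1.0", call. = FALSE)
    }
  })
  invisible(bundle)
}

bundle_age_range <- function(bundle) range(bundle$lms$age_months)

# Snap ages (months) to the bundle grid: nearest record, ties to younger.
snap_age <- function(bundle, age_months) {
  ages <- sort(unique(bundle$lms$age_months))
  rng <- range(ages)
  bad <- age_months < rng[1] | age_months > rng[2]
  if (any(bad)) {
    stop("age ", age_months[which(bad)[1]], " months outside the reference ",
         "grid [", rng[1], ", ", rng[2], "]", call. = FALSE)
  }
  # Nearest grid age, ties to the younger age.
  pos <- findInterval(age_months, ages, all.inside = TRUE)
  lo <- ages[pos]
  hi <- ages[pmin(pos + 1L, length(ages))]
  ifelse(age_months - lo <= hi - age_months, lo, hi)
}

#' Look up the LMS record for an age and sex
#'
#' Returns the record at the nearest grid age (ties resolved to the younger
#' age). Ages outside the bundle's grid are an error.
#'
#' @param bundle A `reference_bundle`.
#' @param age_months Age(s) in months.
#' @param sex `"male"` or `"female"` (recycled to the length of `age_months`).
#' @return A data frame with columns `age_months`, `sex`, `L`, `M`, `S`,
#'   one row per queried age.
#' @export
lookup_lms <- function(bundle, age_months, sex) {
  stopifnot(inherits(bundle, "reference_bundle"))
  n <- max(length(age_months), length(sex))
  age_months <- rep_len(age_months, n)
  sex <- rep_len(sex, n)
  snapped <- snap_age(bundle, age_months)
  key <- paste(bundle$lms$age_months, bundle$lms$sex)
  rows <- match(paste(snapped, sex), key)
  if (anyNA(rows)) stop("unknown sex value in lookup_lms", call. = FALSE)
  out <- bundle$lms[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal analogue for the growth table (velocity, median height, cv).
lookup_growth <- function(bundle, age_months, sex) {
  n <- max(length(age_months), length(sex))
  age_months <- rep_len(age_months, n)
  sex <- rep_len(sex, n)
  snapped <- snap_age(bundle, age_months)
  key <- paste(bundle$growth$age_months, bundle$growth$sex)
  rows <- match(paste(snapped, sex), key)
  out <- bundle$growth[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Activity pattern rows for one town, as a named list segment -> (met, min).
activity_pattern <- function(bundle, town_type) {
  sub <- bundle$activity[bundle$activity$town_type == town_type, ]
  if (nrow(sub) == 0L) {
    stop("no activity pattern for town type ", town_type, call. = FALSE)
  }
  split(sub[, c("met_level", "minutes")], sub$segment)
}

#' Write a reference bundle to a JSON file
#'
#' The file holds arrays `lms`, `growth` and `activity` plus the scalar
#' multiplier fields and a `version` field; [read_bundle()] restores it
#' losslessly (full double precision).
#'
#' @param bundle A `reference_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  out <- unclass(bundle)
  # named atomic vectors lose their names as JSON arrays; keep towns keyed
  out$intake_multiplier_mean <- as.list(out$intake_multiplier_mean)
  jsonlite::write_json(out, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a reference bundle from a JSON file
#'
#' @param path Path to a file written by [write_bundle()].
#' @return A validated `reference_bundle`.
#' @export
read_bundle <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$version)) {
    stop("not a reference bundle: missing version field", call. = FALSE)
  }
  bundle <- structure(list(
    version = raw$version,
    profile = raw$profile,
    seed = as.integer(raw$seed),
    lms = as.data.frame(raw$lms),
    growth = as.data.frame(raw$growth),
    activity = as.data.frame(raw$activity),
    intake_multiplier_mean = unlist(raw$intake_multiplier_mean),
    intake_multiplier_sd = as.numeric(raw$intake_multiplier_sd)
  ), class = "reference_bundle")
  bundle$lms$age_months <- as.integer(bundle$lms$age_months)
  bundle$growth$age_months <- as.integer(bundle$growth$age_months)
  validate_bundle(bundle)
  bundle
}

#' @export
print.reference_bundle <- function(x, ...) {
  rng <- bundle_age_range(x)
  cat("<reference_bundle> profile:", x$profile, " version:", x$version, "\n")
  cat("  LMS grid:", rng[1], "-", rng[2], "months x", length(SEXES), "sexes\n")
  cat("  intake multiplier mean:",
      paste(sprintf("%s=%.2f", names(x$intake_multiplier_mean),
                    x$intake_multiplier_mean), collapse = " "),
      " sd:", x$intake_multiplier_sd, "\n")
  invisible(x)
}
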