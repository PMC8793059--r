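#' Read a long-format time-lapse measurement table
#'
#' Reads a CSV of time-lapse surface-coverage measurements, one row per
#' experiment x field of view (FOV) x condition x time point, validates it,
#' and returns a tibble with a derived `log_area` column (base-10 log of the
#' thresholded fluorescence area).
#'
#' The required columns are `experiment_id`, `fov_id`, `condition`, `time_h`
#' and `area`. Any further columns (e.g. inoculum level) are carried through
#' untouched. `condition` is free text; analyses that contrast treated
#' against control series select the two labels explicitly.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated tibble of measurements (see [validate_timelapse()]).
#' @seealso [write_timelapse_csv()], [simulate_growth()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_timelapse_csv(simulate_growth(2, 2, seed = 1), tf)
#' head(read_timelapse_csv(tf))
read_timelapse_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    abort(paste0("empty measurement file: ", path))
  }
  validate_timelapse(df)
}

#' Write a time-lapse measurement table to CSV
#'
#' The inverse of [read_timelapse_csv()]; a write/read round trip is lossless
#' for the precision retained by the CSV text representation.
#'
#' @param data A measurement tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timelapse_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a long-format measurement table
#'
#' Checks the measurement invariants: required columns present, every `area`
#' strictly positive, non-negative times, no duplicated
#' (experiment, FOV, condition, time) keys, and strictly increasing time
#' within each series. Offending rows are reported by row number. A
#' `log_area` column is added (or checked, if already present).
#'
#' @param data A data frame of measurements.
#' @return The data as a tibble with `log_area`, invisibly checkable.
#' @export
validate_timelapse <- function(data) {
  required <- c("experiment_id", "fov_id", "condition", "time_h", "area")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("measurement table is empty")

  bad_area <- which(!is.finite(data$area) | data$area <= 0)
  if (length(bad_area) > 0) {
    abort(paste0(
      "non-positive or missing area in row(s): ",
      paste(head(bad_area, 10L), collapse = ", "),
      if (length(bad_area) > 10L) " ..." else ""
    ))
  }
  bad_time <- which(!is.finite(data$time_h) | data$time_h < 0)
  if (length(bad_time) > 0) {
    abort(paste0(
      "negative or missing time_h in row(s): ",
      paste(head(bad_time, 10L), collapse = ", ")
    ))
  }

  key <- paste(data$experiment_id, data$fov_id, data$condition, data$time_h,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0(
      "duplicated (experiment_id, fov_id, condition, time_h) in row(s): ",
      paste(head(dup, 10L), collapse = ", ")
    ))
  }

  # duplicated times within a series are caught by the key check above;
  # row order in the file is not assumed (series are sorted downstream)

  if ("log_area" %in% names(data)) {
    off <- which(abs(data$log_area - log10(data$area)) > 1e-6)
    if (length(off) > 0) {
      abort(paste0("log_area inconsistent with log10(area) in row(s): ",
                   paste(head(off, 10L), collapse = ", ")))
    }
  } else {
    data$log_area <- log10(data$area)
  }
  data
}

#' Published per-phase repeatability profiles for early S. aureus biofilms
#'
#' Repeatability standard deviation of log10 surface coverage for each growth
#' phase of untreated early-colonization biofilms, with the proportion of
#' variance attributable to experiment, field of view and time, the lag-1
#' serial correlation of within-series residuals, and the implied variance
#' inflation factor. These profiles summarise a large reference dataset of
#' confocal time-lapse experiments and are the packaged starting point for
#' design assessment when no pilot data are available.
#'
#' @param phase Optional phase name (`"lag"`, `"early"`, `"late"`,
#'   case-insensitive) to return a single row.
#' @return A tibble with columns `phase`, `t_start`, `t_end`,
#'   `prop_exp`, `prop_fov`, `prop_time`, `repeatability_sd`, `r`, `c`.
#' @seealso [phase_profile_to_components()]
#' @export
#' @examples
#' phase_profiles()
#' phase_profiles("early")
phase_profiles <- function(phase = NULL) {
  profiles <- tibble::tribble(
    ~phase,  ~t_start, ~t_end, ~prop_exp, ~prop_fov, ~prop_time, ~repeatability_sd, ~r,     ~c,
    "lag",   0,        2,      0.3207,    0.6707,    0.0086,     0.4867,            0.8313, 10.9,
    "early", 2,        4,      0.5831,    0.4033,    0.0137,     0.3186,            0.8751, 15.0,
    "late",  4,        8,      0.4540,    0.5151,    0.0309,     0.2148,            0.9129, 22.0
  )
  if (is.null(phase)) {
    return(profiles)
  }
  hit <- profiles[tolower(profiles$phase) == tolower(phase), ]
  if (nrow(hit) != 1) {
    abort(paste0("unknown phase '", phase, "'; choose one of: ",
                 paste(profiles$phase, collapse = ", ")))
  }
  hit
}

#' Construct a variance-components row
#'
#' The universal currency of design assessment: variances of the experiment,
#' FOV-within-experiment and time (residual) levels, in squared log10 units,
#' plus the lag-1 serial correlation `r` of within-series residuals and the
#' variance inflation factor `c = (1 + r) / (1 - r)`. The inflation factor is
#' stored un-applied; it enters only when a design is evaluated.
#'
#' @param var_exp,var_fov,var_time Non-negative variances (squared log10 units).
#' @param r Lag-1 serial correlation in (-1, 1), or `NA` when unknown.
#' @param c Variance inflation factor; defaults to `(1 + r) / (1 - r)` when
#'   `r` is given, `NA` otherwise. Conventionally set to 12 for log-reduction
#'   designs when not estimated.
#' @param provenance One of `"fitted"`, `"from_profile"`, `"user_supplied"`.
#' @param n_obs Number of observations behind the estimate, if known.
#' @return A one-row tibble with the fields above.
#' @export
#' @examples
#' variance_components(0.059, 0.041, 0.0014, r = 0.8751)
variance_components <- function(var_exp, var_fov, var_time,
                                r = NA_real_, c = NULL,
                                provenance = "user_supplied",
                                n_obs = NA_integer_) {
  stopifnot(length(var_exp) == 1, length(var_fov) == 1, length(var_time) == 1)
  if (any(c(var_exp, var_fov, var_time) < 0, na.rm = TRUE)) {
    abort("variance components must be non-negative")
  }
  if (!is.na(r) && (r <= -1 || r >= 1)) {
    abort("serial correlation r must lie strictly inside (-1, 1)")
  }
  if (is.null(c)) {
    c <- if (is.na(r)) NA_real_ else inflation_factor(r)
  }
  if (!is.na(c) && c < 0) abort("inflation factor c must be non-negative")
  provenance <- match.arg(provenance,
                          c("user_supplied", "fitted", "from_profile"))
  tibble(
    var_exp = as.numeric(var_exp),
    var_fov = as.numeric(var_fov),
    var_time = as.numeric(var_time),
    r = as.numeric(r),
    c = as.numeric(c),
    provenance = provenance,
    n_obs = as.integer(n_obs)
  )
}

#' Convert a phase profile to variance components
#'
#' Reconstitutes the level-wise variances from a published phase profile as
#' proportion x (repeatability SD)^2. The inflation factor is copied, not
#' pre-applied to the time component: the profile's repeatability SD squared
#' equals the plain sum of the three components, and `c` multiplies the time
#' term only when a design is evaluated (the convention under which the
#' published worked example reproduces).
#'
#' @param profile A one-row profile tibble as returned by [phase_profiles()],
#'   or a phase name passed through to [phase_profiles()].
#' @return A one-row variance-components tibble (see [variance_components()]).
#' @export
#' @examples
#' phase_profile_to_components("early")
phase_profile_to_components <- function(profile) {
  if (is.character(profile)) profile <- phase_profiles(profile)
  stopifnot(is.data.frame(profile), nrow(profile) == 1)
  needed <- c("prop_exp", "prop_fov", "prop_time", "repeatability_sd", "r", "c")
  missing <- setdiff(needed, names(profile))
  if (length(missing) > 0) {
    abort(paste0("profile lacks column(s): ", paste(missing, collapse = ", ")))
  }
  psum <- profile$prop_exp + profile$prop_fov + profile$prop_time
  if (abs(psum - 1) > 0.01) {
    warn(sprintf("variance proportions sum to %.4f, not ~1", psum))
  }
  s2 <- profile$repeatability_sd^2
  variance_components(
    var_exp = profile$prop_exp * s2,
    var_fov = profile$prop_fov * s2,
    var_time = profile$prop_time * s2,
    r = profile$r,
    c = profile$c,
    provenance = "from_profile"
  )
}

# Coerce fitted objects / profiles to a variance-components row.
as_variance_components <- function(x) {
  if (inherits(x, "vc_fit")) return(x$components)
  if (is.data.frame(x) && all(c("var_exp", "var_fov", "var_time") %in% names(x))) {
    stopifnot(nrow(x) == 1)
    return(x)
  }
  if (is.data.frame(x) && "repeatability_sd" %in% names(x)) {
    return(phase_profile_to_components(x))
  }
  abort("cannot interpret input as variance components")
}
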