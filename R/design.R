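#' One-sided t multiplier for a design
#'
#' The 95th percentile (or `conf` quantile) of Student's t distribution with
#' `n_exp - 1` degrees of freedom, used to turn a standard error into a
#' one-sided margin of error. With a single experiment the usual degrees of
#' freedom vanish; the convention adopted here is a t distribution with 0.5
#' degrees of freedom, giving an approximate (and deliberately very wide)
#' margin. Fractional degrees of freedom are handled exactly by [stats::qt()].
#'
#' @param n_exp Number of independent experiments (integer >= 1); vectorized.
#' @param conf One-sided confidence level (default 0.95).
#' @return The t quantile(s).
#' @export
#' @examples
#' t_multiplier(c(1, 2, 6))
t_multiplier <- function(n_exp, conf = 0.95) {
  if (any(!is.finite(n_exp)) || any(n_exp < 1) || any(n_exp != floor(n_exp))) {
    abort("n_exp must be integer >= 1")
  }
  stopifnot(conf > 0, conf < 1)
  df <- ifelse(n_exp == 1, 0.5, n_exp - 1)
  qt(conf, df = df)
}

resolve_c <- function(vc, c) {
  if (!is.null(c)) {
    if (!is.finite(c) || c < 0) abort("inflation factor c must be >= 0")
    return(c)
  }
  if (is.null(vc$c) || is.na(vc$c)) {
    abort(paste0(
      "no inflation factor available: supply c explicitly ",
      "(c = 1 for uncorrelated frames; c = 12 is the convention for ",
      "log-reduction designs when not estimated)"
    ))
  }
  vc$c
}

check_design <- function(n_exp, n_fov, n_time) {
  for (nm in c("n_exp", "n_fov", "n_time")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 1) || any(v != floor(v))) {
      abort(paste0(nm, " must be a positive integer"))
    }
  }
}

#' Standard error of the mean for a candidate design
#'
#' Predicts the standard error of the mean response — mean log10 area of
#' untreated biofilm, or mean log reduction — for a design with `n_exp`
#' experiments, `n_fov` fields of view per experiment, and `n_time` frames
#' per FOV in the analysis window:
#' \deqn{SEM = \sqrt{\frac{Var_{exp}}{n_{exp}} +
#'   \frac{Var_{FOV}}{n_{exp} n_{FOV}} +
#'   \frac{Var_{time}\,c}{n_{exp} n_{FOV} n_{time}}}}
#' The inflation factor `c` accounts for lag-1 serial correlation of frames
#' within a series; `c = 1` recovers the classic balanced-design SEM.
#' Single-snapshot designs are the special case `n_time = 1`.
#'
#' @param vc A one-row variance-components tibble (from
#'   [variance_components()], [phase_profile_to_components()], or a
#'   [fit_components()] result).
#' @param n_exp,n_fov,n_time Design counts; vectorized in parallel.
#' @param c Inflation factor override; defaults to the value stored in `vc`.
#' @return SEM in the units of the response (log10).
#' @export
#' @examples
#' vc <- phase_profile_to_components("early")
#' design_sem(vc, n_exp = 2, n_fov = 3, n_time = 20)  # 0.191
design_sem <- function(vc, n_exp, n_fov, n_time, c = NULL) {
  vc <- as_variance_components(vc)
  c <- resolve_c(vc, c)
  check_design(n_exp, n_fov, n_time)
  sqrt(vc$var_exp / n_exp +
         vc$var_fov / (n_exp * n_fov) +
         vc$var_time * c / (n_exp * n_fov * n_time))
}

#' Repeatability standard deviation
#'
#' The SD of single measurements pooled across experiments, FOVs and frames,
#' inflated for within-series serial correlation:
#' `sqrt(Var_exp + Var_FOV + Var_time * c)`. Equals the SEM of the 1x1x1
#' design at the same `c`.
#'
#' @inheritParams design_sem
#' @return Repeatability SD (log10 units).
#' @export
repeatability_sd <- function(vc, c = NULL) {
  vc <- as_variance_components(vc)
  c <- resolve_c(vc, c)
  sqrt(vc$var_exp + vc$var_fov + vc$var_time * c)
}

#' Margin of error of a candidate design
#'
#' Assesses one design: SEM, degrees of freedom, one-sided t multiplier and
#' the margin of error `MOE = t x SEM` of a one-sided confidence interval
#' for the mean. The lower confidence limit for an observed mean is
#' `mean - MOE`; a treatment kill is declared significant when
#' `mean LR - MOE > 0`.
#'
#' @inheritParams design_sem
#' @param conf One-sided confidence level (default 0.95).
#' @return A tibble with one row per design: `n_exp`, `n_fov`, `n_time`,
#'   `sem`, `df`, `t_mult`, `moe`.
#' @export
#' @examples
#' vc <- phase_profile_to_components("early")
#' design_moe(vc, n_exp = 3, n_fov = 2, n_time = 10)
design_moe <- function(vc, n_exp, n_fov, n_time, c = NULL, conf = 0.95) {
  vc <- as_variance_components(vc)
  n <- vctrs_recycle(n_exp, n_fov, n_time)
  sem <- design_sem(vc, n$n_exp, n$n_fov, n$n_time, c = c)
  t_mult <- t_multiplier(n$n_exp, conf = conf)
  tibble(
    n_exp = n$n_exp, n_fov = n$n_fov, n_time = n$n_time,
    sem = sem,
    df = ifelse(n$n_exp == 1, 0.5, n$n_exp - 1),
    t_mult = t_mult,
    moe = t_mult * sem
  )
}

# recycle the three design vectors to a common length
vctrs_recycle <- function(n_exp, n_fov, n_time) {
  len <- max(length(n_exp), length(n_fov), length(n_time))
  list(n_exp = rep_len(n_exp, len), n_fov = rep_len(n_fov, len),
       n_time = rep_len(n_time, len))
}

#' Margin-of-error grid over candidate designs
#'
#' Evaluates [design_moe()] over the full cross product of design counts,
#' ordered with `n_exp` outermost and `n_time` innermost to mirror the
#' conventional design-table layout.
#'
#' @inheritParams design_moe
#' @param n_exp,n_fov,n_time Vectors of candidate counts.
#' @return A tibble of assessments, one row per grid cell.
#' @seealso [grid_table()] for the wide layout.
#' @export
#' @examples
#' vc <- phase_profile_to_components("early")
#' design_grid(vc, n_exp = 1:3, n_fov = c(1, 2, 6), n_time = c(10, 40))
design_grid <- function(vc, n_exp, n_fov, n_time, c = NULL, conf = 0.95) {
  stopifnot(length(n_exp) > 0, length(n_fov) > 0, length(n_time) > 0)
  grid <- tidyr::expand_grid(n_exp = n_exp, n_fov = n_fov, n_time = n_time)
  design_moe(vc, grid$n_exp, grid$n_fov, grid$n_time, c = c, conf = conf)
}

#' Pivot a design grid into the conventional wide table
#'
#' One row per `n_exp`, one column per (FOV, frames) combination, cells
#' holding the MOE.
#'
#' @param grid A tibble from [design_grid()].
#' @param value Column to spread (default `"moe"`).
#' @return A wide tibble.
#' @export
grid_table <- function(grid, value = "moe") {
  stopifnot(value %in% names(grid))
  grid %>%
    mutate(col = sprintf("fov%d_f%d", .data$n_fov, .data$n_time)) %>%
    select("n_exp", "col", all_of(value)) %>%
    tidyr::pivot_wider(names_from = "col", values_from = all_of(value)) %>%
    arrange(.data$n_exp)
}

#' Smallest number of experiments meeting a design criterion
#'
#' Searches `n_exp = 1, 2, ...` for the smallest design meeting either an
#' absolute margin-of-error bound (`moe_below`) or detection of an expected
#' log reduction (`detect_lr`: the one-sided lower limit `LR - MOE` must be
#' strictly positive).
#'
#' @inheritParams design_moe
#' @param n_fov,n_time Fixed FOV and frame counts for the search.
#' @param moe_below MOE threshold (exclusive), or `NULL`.
#' @param detect_lr Expected mean LR to detect, or `NULL`. Exactly one of
#'   `moe_below` / `detect_lr` must be given.
#' @param max_exp Upper search bound.
#' @return The smallest qualifying `n_exp`, or `NA` (with a warning) when
#'   none up to `max_exp` qualifies.
#' @export
#' @examples
#' vc <- phase_profile_to_components("early")
#' min_experiments(vc, n_fov = 2, n_time = 10, moe_below = 1)  # 3
min_experiments <- function(vc, n_fov, n_time, moe_below = NULL,
                            detect_lr = NULL, c = NULL, conf = 0.95,
                            max_exp = 100) {
  if (is.null(moe_below) == is.null(detect_lr)) {
    abort("supply exactly one of moe_below or detect_lr")
  }
  stopifnot(max_exp >= 1)
  assess <- design_moe(vc, n_exp = seq_len(max_exp), n_fov = n_fov,
                       n_time = n_time, c = c, conf = conf)
  ok <- if (!is.null(moe_below)) {
    assess$moe < moe_below
  } else {
    detect_lr - assess$moe > 0  # ties at exactly 0 are not detected
  }
  if (!any(ok)) {
    warn(paste0("no design with n_exp <= ", max_exp, " meets the criterion"))
    return(NA_integer_)
  }
  as.integer(assess$n_exp[which(ok)[1]])
}

#' Percent reduction in margin of error between two designs
#'
#' `100 * (MOE_a - MOE_b) / MOE_a`: the relative precision gained by moving
#' from design a to design b.
#'
#' @param a,b Either numeric MOEs or one-row assessment tibbles from
#'   [design_moe()].
#' @return Percent reduction (positive when b is more precise).
#' @export
#' @examples
#' vc <- phase_profile_to_components("early")
#' percent_moe_reduction(design_moe(vc, 2, 2, 10), design_moe(vc, 3, 2, 10))
percent_moe_reduction <- function(a, b) {
  get_moe <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1, "moe" %in% names(x))
      x$moe
    } else {
      as.numeric(x)
    }
  }
  moe_a <- get_moe(a)
  moe_b <- get_moe(b)
  if (!is.finite(moe_a) || moe_a <= 0) {
    abort("reference margin of error must be positive")
  }
  100 * (moe_a - moe_b) / moe_a
}
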