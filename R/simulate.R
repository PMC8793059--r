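#' Simulate nested time-lapse growth data
#'
#' Generates a long-format measurement table with the statistical structure
#' the analysis assumes: a piecewise-linear mean log10 area trajectory (a lag
#' phase followed by an exponential phase), a Normal random intercept per
#' experiment, a Normal random intercept per FOV within experiment, and a
#' stationary AR(1) residual within each FOV series. Areas are emitted as
#' `10^log_area`.
#'
#' Default parameters emulate early S. aureus colonization: a 4-h time
#' course at one frame per 3 min, shallow lag growth for the first 2 h, then
#' ~0.5 log10/h exponential growth, with level SDs (0.243, 0.202, 0.037
#' log10 units) and lag-1 correlation 0.8751 matching the early-exponential
#' repeatability profile of the packaged reference dataset.
#'
#' @param n_exp,n_fov Numbers of experiments and FOVs per experiment.
#' @param baseline_log_area Mean log10 area at t = 0.
#' @param lag_slope,exp_slope Mean slopes (log10 units/h) before and after
#'   `lag_end_h`.
#' @param lag_end_h Phase-change time (h); 0 gives a single linear phase.
#' @param sd_exp,sd_fov,sd_time SDs (log10 units) of the experiment effect,
#'   FOV effect, and the stationary AR(1) residual.
#' @param phi AR(1) coefficient in (-1, 1); residuals are initialized from
#'   the stationary distribution so the first frame is not down-weighted.
#' @param frame_interval_h Frame spacing in hours (3-min frames = 0.05).
#' @param duration_h Total imaging duration (h).
#' @param start_h Time of the first frame (h).
#' @param condition Condition label stamped on every row.
#' @param seed Optional RNG seed; the dataset is reproducible given the seed.
#' @return A validated measurement tibble.
#' @export
#' @examples
#' d <- simulate_growth(3, 2, seed = 1)
#' dplyr::count(d, experiment_id, fov_id)
simulate_growth <- function(n_exp, n_fov,
                            baseline_log_area = 2.5,
                            lag_slope = 0.1,
                            exp_slope = 0.5,
                            lag_end_h = 2,
                            sd_exp = 0.2433,
                            sd_fov = 0.2023,
                            sd_time = 0.0373,
                            phi = 0.8751,
                            frame_interval_h = 0.05,
                            duration_h = 4,
                            start_h = 0,
                            condition = "control",
                            seed = NULL) {
  check_sim_params(sd_exp, sd_fov, sd_time, phi, frame_interval_h, duration_h)
  stopifnot(n_exp >= 1, n_fov >= 1)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(start_h, start_h + duration_h, by = frame_interval_h)
  b_exp <- rnorm(n_exp, 0, sd_exp)
  sim_fovs(
    exp_ids = sprintf("exp%02d", seq_len(n_exp)),
    fov_prefix = "fov",
    n_fov = n_fov, times = times, b_exp = b_exp,
    mean_fun = function(t) growth_mean(t, baseline_log_area, lag_slope,
                                       exp_slope, lag_end_h),
    sd_fov = sd_fov, sd_time = sd_time, phi = phi,
    condition = condition
  ) %>% validate_timelapse()
}

growth_mean <- function(t, baseline, lag_slope, exp_slope, lag_end) {
  baseline + lag_slope * pmin(t, lag_end) + exp_slope * pmax(t - lag_end, 0)
}

check_sim_params <- function(sd_exp, sd_fov, sd_time, phi,
                             frame_interval_h, duration_h) {
  if (any(c(sd_exp, sd_fov, sd_time) < 0)) abort("SDs must be >= 0")
  if (abs(phi) >= 1) abort("phi must satisfy |phi| < 1")
  if (frame_interval_h <= 0 || duration_h <= 0 ||
      frame_interval_h > duration_h) {
    abort("need 0 < frame_interval_h <= duration_h")
  }
}

# stationary AR(1): e_1 ~ N(0, sd^2); innovations scaled to keep the
# marginal SD at sd for every t
ar1_series <- function(n, sd, phi) {
  if (sd == 0) return(rep(0, n))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  init <- rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = init))
}

sim_fovs <- function(exp_ids, fov_prefix, n_fov, times, b_exp, mean_fun,
                     sd_fov, sd_time, phi, condition) {
  mu <- mean_fun(times)
  purrr::map2(exp_ids, b_exp, function(eid, be) {
    purrr::map(seq_len(n_fov), function(j) {
      bf <- rnorm(1, 0, sd_fov)
      e <- ar1_series(length(times), sd_time, phi)
      tibble(
        experiment_id = eid,
        fov_id = sprintf("%s%02d", fov_prefix, j),
        condition = condition,
        time_h = times,
        log_area = mu + be + bf + e
      )
    }) %>% list_rbind()
  }) %>%
    list_rbind() %>%
    mutate(area = 10^.data$log_area) %>%
    select("experiment_id", "fov_id", "condition", "time_h", "area",
           "log_area")
}

#' Simulate a paired control/treated time-lapse study
#'
#' Control FOVs follow [simulate_growth()]; treated FOVs share each
#' experiment's random intercept (control and treated wells sit in the same
#' dish) but have the target log-reduction curve subtracted from their mean
#' log10 trajectory and draw independent FOV- and time-level noise. As a
#' consequence [compute_lr()] recovers the target LR in expectation.
#'
#' @inheritParams simulate_growth
#' @param n_control_fov,n_treated_fov FOVs per experiment in the control and
#'   treated wells.
#' @param treatment_lr Target mean log reduction: a scalar (constant in
#'   time) or a function of time in hours.
#' @return A validated measurement tibble with `condition` equal to
#'   `"control"` or `"treated"`.
#' @export
#' @examples
#' d <- simulate_paired_study(3, 2, 2, treatment_lr = 0.8, seed = 2)
#' mean_lr(compute_lr(d), window = c(3, 4))
simulate_paired_study <- function(n_exp, n_control_fov, n_treated_fov,
                                  treatment_lr = 0,
                                  baseline_log_area = 2.5,
                                  lag_slope = 0.1,
                                  exp_slope = 0.5,
                                  lag_end_h = 2,
                                  sd_exp = 0.2433,
                                  sd_fov = 0.2023,
                                  sd_time = 0.0373,
                                  phi = 0.8751,
                                  frame_interval_h = 0.05,
                                  duration_h = 4,
                                  start_h = 0,
                                  seed = NULL) {
  check_sim_params(sd_exp, sd_fov, sd_time, phi, frame_interval_h, duration_h)
  stopifnot(n_exp >= 1, n_control_fov >= 1, n_treated_fov >= 1)
  if (!is.null(seed)) set.seed(seed)
  lr_fun <- if (is.function(treatment_lr)) {
    treatment_lr
  } else {
    function(t) rep_len(treatment_lr, length(t))
  }
  times <- seq(start_h, start_h + duration_h, by = frame_interval_h)
  exp_ids <- sprintf("exp%02d", seq_len(n_exp))
  b_exp <- rnorm(n_exp, 0, sd_exp)
  base_mean <- function(t) growth_mean(t, baseline_log_area, lag_slope,
                                       exp_slope, lag_end_h)
  controls <- sim_fovs(exp_ids, "c", n_control_fov, times, b_exp,
                       base_mean, sd_fov, sd_time, phi, "control")
  treated <- sim_fovs(exp_ids, "t", n_treated_fov, times, b_exp,
                      function(t) base_mean(t) - lr_fun(t),
                      sd_fov, sd_time, phi, "treated")
  bind_rows(controls, treated) %>% validate_timelapse()
}
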