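#' Lag-1 serial correlation of within-series residuals
#'
#' Pooled first serial correlation coefficient over a set of residual time
#' series:
#' \deqn{r = \frac{\sum_{series}\sum_{t=2}^{n} res_t\, res_{t-1}}
#'            {\sum_{series}\sum_{t=1}^{n} res_t^2}}
#' Numerators are summed within series only — lagged products never straddle
#' a series boundary — and the denominator is the full pooled sum of squares
#' (t = 1..n). The estimate is clamped to (-1 + eps, 1 - eps) with a warning
#' if it falls outside.
#'
#' @param residuals A tibble with columns `experiment_id`, `fov_id`,
#'   `time_h` and `resid` (model residuals in log10 units), or a numeric
#'   vector for a single series.
#' @return The pooled lag-1 serial correlation.
#' @seealso [inflation_factor()], [fit_components()]
#' @export
#' @examples
#' serial_correlation(c(1, -1, 1, -1))  # -0.75
serial_correlation <- function(residuals) {
  if (is.numeric(residuals)) {
    residuals <- tibble(experiment_id = "e", fov_id = "f",
                        time_h = seq_along(residuals), resid = residuals)
  }
  stopifnot(is.data.frame(residuals),
            all(c("experiment_id", "fov_id", "resid") %in% names(residuals)))
  series <- residuals %>%
    group_by(.data$experiment_id, .data$fov_id) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(
      num = sum(.data$resid[-1] * .data$resid[-length(.data$resid)]),
      den = sum(.data$resid^2),
      len = length(.data$resid),
      .groups = "drop"
    )
  if (all(series$len < 2)) {
    abort("serial correlation needs at least one series of length >= 2")
  }
  # length-1 series contribute only to the denominator, consistent with the
  # pooled t = 1..n sum of squares
  den <- sum(series$den)
  if (den == 0) abort("all residuals are zero; serial correlation undefined")
  r <- sum(series$num) / den
  eps <- 1e-8
  if (r <= -1 + eps || r >= 1 - eps) {
    warn(sprintf("serial correlation %.6f clamped into (-1, 1)", r))
    r <- max(min(r, 1 - eps), -1 + eps)
  }
  r
}

#' AR(1) variance inflation factor
#'
#' The factor `c = (1 + r) / (1 - r)` by which the time-level variance is
#' inflated to account for lag-1 serial correlation within a series, in the
#' classic adjust-after-fitting treatment of serially correlated residuals.
#'
#' @param r Lag-1 serial correlation, strictly inside (-1, 1).
#' @return The inflation factor (dimensionless, >= 0; equals 1 at `r = 0`).
#' @export
#' @examples
#' inflation_factor(0.8751)  # ~15
inflation_factor <- function(r) {
  if (any(!is.finite(r)) || any(r <= -1) || any(r >= 1)) {
    abort("serial correlation r must lie strictly inside (-1, 1)")
  }
  (1 + r) / (1 - r)
}

#' Estimate nested variance components from time-lapse data
#'
#' Fits a linear mixed model to log10 area (or any response column) with
#' random intercepts for experiment and for FOV nested in experiment, and a
#' fixed linear time trend (extendable with further covariates). Variance
#' components are estimated by REML via \pkg{lme4}; on perfectly balanced
#' designs a method-of-moments expected-mean-square estimator is available
#' and agrees with REML. Conditional residuals are returned per FOV series
#' and the pooled lag-1 serial correlation and inflation factor are computed
#' from them.
#'
#' @param data A measurement tibble.
#' @param window Optional time window `c(t0, t1)` (hours, closed) to subset
#'   before fitting, e.g. one growth phase.
#' @param fixed One-sided formula for the fixed part (default `~ time_h`).
#'   Covariates such as log inoculum or phase indicators and their
#'   interactions with time may be added, mirroring the pooled-phase model.
#' @param response Response column name (default `"log_area"`).
#' @param method `"reml"` (default) or `"moments"` (balanced designs only).
#' @return An object of class `vc_fit`: a list with `components` (a one-row
#'   variance-components tibble including `r` and `c`), `residuals` (tibble
#'   `experiment_id`, `fov_id`, `time_h`, `resid`), and `fit` (the underlying
#'   model object). Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' d <- simulate_growth(4, 2, duration_h = 1, lag_end_h = 0, seed = 7)
#' fit <- fit_components(d)
#' glance(fit)
fit_components <- function(data, window = NULL, fixed = ~time_h,
                           response = "log_area",
                           method = c("reml", "moments")) {
  method <- match.arg(method)
  data <- validate_timelapse(data)
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' not found"))
  }
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    data <- data %>%
      filter(.data$time_h >= window[1], .data$time_h <= window[2])
    if (nrow(data) == 0) abort("no measurements fall in the window")
  }
  n_exp <- n_distinct(data$experiment_id)
  if (n_exp < 2) {
    abort(paste0(
      "only ", n_exp, " experiment present: the experiment-level variance ",
      "is inestimable; supply var_exp directly via variance_components()"
    ))
  }
  series_len <- data %>%
    count(.data$experiment_id, .data$fov_id, .data$condition)
  if (any(series_len$n < 2)) {
    abort("every FOV series needs at least 2 time points within the window")
  }
  data <- data %>%
    mutate(.series = paste(.data$experiment_id, .data$fov_id, .data$condition,
                           sep = ":")) %>%
    arrange(.data$experiment_id, .data$fov_id, .data$condition, .data$time_h)

  if (var(data[[response]]) == 0) {
    # constant response: every component is exactly zero and the mixed model
    # is degenerate
    comps <- variance_components(0, 0, 0, r = 0, c = 1,
                                 provenance = "fitted", n_obs = nrow(data))
    res <- data %>%
      mutate(resid = 0) %>%
      select("experiment_id", "fov_id", "time_h", "resid")
    return(structure(list(components = comps, residuals = res, fit = NULL,
                          method = method), class = "vc_fit"))
  }

  if (method == "reml") {
    rhs <- paste(deparse(fixed[[2]]), collapse = " ")
    fml <- as.formula(paste0(
      response, " ~ ", rhs,
      " + (1 | experiment_id) + (1 | experiment_id:fov_id)"
    ))
    fit <- lme4::lmer(fml, data = data, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    vc_tab <- as.data.frame(lme4::VarCorr(fit))
    get_v <- function(g) {
      v <- vc_tab$vcov[vc_tab$grp == g]
      if (length(v) != 1) abort(paste0("variance for '", g, "' not found"))
      max(v, 0)
    }
    var_exp <- get_v("experiment_id")
    var_fov <- get_v("experiment_id:fov_id")
    var_time <- get_v("Residual")
    res <- data %>%
      mutate(resid = resid(fit)) %>%
      select("experiment_id", "fov_id", "time_h", "resid")
  } else {
    out <- moments_components(data, fixed, response)
    var_exp <- out$var_exp
    var_fov <- out$var_fov
    var_time <- out$var_time
    fit <- out$fit
    res <- out$residuals
  }

  r <- serial_correlation(res)
  comps <- variance_components(
    var_exp = var_exp, var_fov = var_fov, var_time = var_time,
    r = r, c = inflation_factor(r),
    provenance = "fitted", n_obs = nrow(data)
  )
  structure(
    list(components = comps, residuals = res, fit = fit, method = method),
    class = "vc_fit"
  )
}

# Expected-mean-square estimator for balanced nested designs: the fixed part
# is removed by OLS, then the nested ANOVA identities give the components.
moments_components <- function(data, fixed, response) {
  counts <- data %>% count(.data$experiment_id, .data$fov_id, .data$condition)
  n_t <- unique(counts$n)
  fov_counts <- counts %>% count(.data$experiment_id)
  n_f <- unique(fov_counts$n)
  if (length(n_t) != 1 || length(n_f) != 1) {
    abort("method = 'moments' requires a perfectly balanced design; use REML")
  }
  n_e <- n_distinct(data$experiment_id)
  rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  ols <- lm(as.formula(paste0(response, " ~ ", rhs)), data = data)
  data$`.res0` <- resid(ols)

  exp_means <- data %>%
    group_by(.data$experiment_id) %>%
    mutate(.m_exp = mean(.data$.res0)) %>%
    group_by(.data$experiment_id, .data$.series) %>%
    mutate(.m_fov = mean(.data$.res0)) %>%
    ungroup()
  grand <- mean(data$`.res0`)

  ms_exp <- n_f * n_t *
    sum((distinct(exp_means, .data$experiment_id, .data$.m_exp)$.m_exp - grand)^2) /
    (n_e - 1)
  fov_tab <- distinct(exp_means, .data$.series, .data$.m_exp, .data$.m_fov)
  ms_fov <- n_t * sum((fov_tab$.m_fov - fov_tab$.m_exp)^2) / (n_e * (n_f - 1))
  ms_within <- sum((exp_means$.res0 - exp_means$.m_fov)^2) /
    (n_e * n_f * (n_t - 1))

  var_time <- ms_within
  var_fov <- (ms_fov - ms_within) / n_t
  var_exp <- (ms_exp - ms_fov) / (n_f * n_t)
  for (nm in c("var_exp", "var_fov")) {
    if (get(nm) < 0) {
      warn(paste0(nm, " estimate negative; truncated to 0"))
    }
  }
  res <- exp_means %>%
    mutate(resid = .data$.res0 - .data$.m_fov) %>%
    select("experiment_id", "fov_id", "time_h", "resid")
  list(var_exp = max(var_exp, 0), var_fov = max(var_fov, 0),
       var_time = var_time, fit = ols, residuals = res)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Nested variance components (", x$method, ")\n", sep = "")
  print(x$components)
  invisible(x)
}

#' @describeIn fit_components One row per variance level with the variance,
#'   SD and proportion of the (uninflated) total.
#' @param x A `vc_fit` object.
#' @param ... Unused.
#' @export
tidy.vc_fit <- function(x, ...) {
  v <- c(x$components$var_exp, x$components$var_fov, x$components$var_time)
  tibble(
    level = c("experiment", "fov", "time"),
    variance = v,
    sd = sqrt(v),
    proportion = if (sum(v) > 0) v / sum(v) else rep(NA_real_, 3)
  )
}

#' @describeIn fit_components One-row summary: components, `r`, `c`, the
#'   inflated repeatability SD, and fit size.
#' @export
glance.vc_fit <- function(x, ...) {
  comps <- x$components
  comps %>%
    mutate(repeatability_sd = repeatability_sd(comps)) %>%
    select("var_exp", "var_fov", "var_time", "r", "c",
           "repeatability_sd", "n_obs")
}
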