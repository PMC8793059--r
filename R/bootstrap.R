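#' Count the distinct single-FOV study draws in a paired dataset
#'
#' A "study draw" picks one control FOV and one treated FOV in every
#' experiment. The number of distinct draws is the product over experiments
#' of (control FOV count) x (treated FOV count) — e.g. 3 experiments with 3
#' control and 3 treated FOVs each give 27 x 27 = 729 draws. The count is
#' computed by the product rule without materializing the draws.
#'
#' @param data A paired measurement tibble.
#' @param control,treated Condition labels.
#' @return The number of distinct draws.
#' @export
n_combinations <- function(data, control = "control", treated = "treated") {
  fovs <- fov_table(data, control, treated)
  prod(fovs$n_control) * prod(fovs$n_treated)
}

fov_table <- function(data, control, treated) {
  data <- validate_timelapse(data)
  present <- unique(data$condition)
  for (lab in c(control, treated)) {
    if (!lab %in% present) {
      abort(paste0("condition label '", lab, "' not present in data"))
    }
  }
  data %>%
    distinct(.data$experiment_id, .data$fov_id, .data$condition) %>%
    group_by(.data$experiment_id) %>%
    summarise(
      n_control = sum(.data$condition == control),
      n_treated = sum(.data$condition == treated),
      .groups = "drop"
    )
}

#' Enumerate all single-FOV study draws
#'
#' Materializes every distinct combination of one control and one treated
#' FOV per experiment. Enumeration requires the full cross product, so FOV
#' counts must be identical across experiments (ragged counts error; use
#' [bootstrap_studies()] for sampled draws instead).
#'
#' @inheritParams n_combinations
#' @return A tibble with one row per (draw, experiment): columns `draw`,
#'   `experiment_id`, `control_fov`, `treated_fov`.
#' @export
#' @examples
#' d <- simulate_paired_study(2, 2, 3, seed = 1)
#' length(unique(enumerate_combinations(d)$draw))  # (2*3)^2 = 36
enumerate_combinations <- function(data, control = "control",
                                   treated = "treated") {
  data <- validate_timelapse(data)
  fovs <- fov_table(data, control, treated)
  if (any(fovs$n_control == 0) || any(fovs$n_treated == 0)) {
    abort("every experiment needs at least one control and one treated FOV")
  }
  if (length(unique(fovs$n_control)) != 1 ||
      length(unique(fovs$n_treated)) != 1) {
    abort(paste0(
      "ragged FOV counts across experiments; ",
      "enumeration requires the full cross product"
    ))
  }
  lookup <- data %>%
    distinct(.data$experiment_id, .data$fov_id, .data$condition)
  exp_ids <- sort(unique(lookup$experiment_id))
  pairs <- purrr::map(exp_ids, function(eid) {
    g <- lookup[lookup$experiment_id == eid, ]
    tidyr::expand_grid(
      control_fov = sort(g$fov_id[g$condition == control]),
      treated_fov = sort(g$fov_id[g$condition == treated])
    )
  })
  idx <- do.call(
    tidyr::expand_grid,
    setNames(purrr::map(pairs, ~seq_len(nrow(.x))),
             paste0(".i", seq_along(pairs)))
  )
  n_draw <- nrow(idx)
  purrr::imap(pairs, function(p, e) {
    k <- idx[[e]]
    tibble(
      draw = seq_len(n_draw),
      experiment_id = exp_ids[e],
      control_fov = p$control_fov[k],
      treated_fov = p$treated_fov[k]
    )
  }) %>%
    list_rbind() %>%
    arrange(.data$draw, .data$experiment_id)
}

# Window means of log10 area per (experiment, fov) for one condition.
window_log_means <- function(data, label, window, right_open) {
  keep <- data$time_h >= window[1] &
    (if (right_open) data$time_h < window[2] else data$time_h <= window[2])
  sub <- data[keep & data$condition == label, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("no '", label, "' measurements fall in the window"))
  }
  sub %>%
    group_by(.data$experiment_id, .data$fov_id) %>%
    summarise(m = mean(.data$log_area), .groups = "drop")
}

# Study statistics for a set of per-experiment mean LRs: the per-study SEM is
# the between-experiment estimator sd / sqrt(n_exp), the single-FOV reduction
# of the design SEM formula.
study_stats <- function(per_exp_lr, conf = 0.95) {
  n <- length(per_exp_lr)
  m <- mean(per_exp_lr)
  sem <- if (n >= 2) sd(per_exp_lr) / sqrt(n) else NA_real_
  t_mult <- t_multiplier(n, conf = conf)
  moe <- t_mult * sem
  tibble(
    mean_lr = m, sem = sem, t_mult = t_mult, moe = moe,
    lower = m - moe, significant = (m - moe) > 0
  )
}

#' Bootstrap simulated studies from a paired dataset
#'
#' Implements the design-validation resampling scheme: each simulated study
#' keeps the experiments fixed and samples, uniformly with replacement
#' within each experiment, the FOVs that a smaller candidate design would
#' have collected (by default one control and one treated FOV). For each
#' study the per-experiment mean LR over the analysis window is computed
#' (control FOVs averaged on the linear area scale), then the study mean LR,
#' the between-experiment SEM (`sd / sqrt(n_exp)`), the one-sided margin of
#' error at `n_exp - 1` degrees of freedom, the lower confidence limit, and
#' whether the study detects a statistically significant kill
#' (`mean LR - MOE > 0`).
#'
#' @inheritParams n_combinations
#' @param n_sim Number of simulated studies.
#' @param window Analysis window `c(t0, t1)` in hours; defaults to the final
#'   hour of the series (a 4-h treatment contact is conventionally read out
#'   over hours 3–4).
#' @param n_control_fov,n_treated_fov FOVs drawn per experiment.
#' @param right_open Exclude the right endpoint of the window.
#' @param conf One-sided confidence level.
#' @param seed Optional RNG seed; results are reproducible given the seed.
#' @return An object of class `bootstrap_validation`: list with `studies`
#'   (one row per simulated study) and `summary` (one row: `n_studies`,
#'   `mean_lr`, `mean_moe`, `median_moe`, `mean_lower`,
#'   `fraction_significant`). Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' d <- simulate_paired_study(3, 3, 3, treatment_lr = 0.8,
#'                            sd_fov = 0.06, sd_time = 0.085, seed = 3)
#' glance(bootstrap_studies(d, n_sim = 200, seed = 4))
bootstrap_studies <- function(data, n_sim = 1000, window = NULL,
                              n_control_fov = 1, n_treated_fov = 1,
                              control = "control", treated = "treated",
                              right_open = FALSE, conf = 0.95, seed = NULL) {
  stopifnot(n_sim >= 1, n_control_fov >= 1, n_treated_fov >= 1)
  data <- validate_timelapse(data)
  if (is.null(window)) {
    t_max <- max(data$time_h)
    window <- c(t_max - 1, t_max)
  }
  stopifnot(length(window) == 2, window[1] <= window[2])
  fovs <- fov_table(data, control, treated)
  if (any(fovs$n_control < 1) || any(fovs$n_treated < 1)) {
    abort("every experiment needs at least one control and one treated FOV")
  }
  if (!is.null(seed)) set.seed(seed)

  # per-FOV window means; control averaging happens on the linear area
  # scale per frame, so precompute per-frame areas for control draws
  keep <- data$time_h >= window[1] &
    (if (right_open) data$time_h < window[2] else data$time_h <= window[2])
  win <- data[keep, , drop = FALSE]
  if (nrow(win) == 0) abort("no measurements fall in the window")

  ctrl_areas <- win %>%
    filter(.data$condition == control) %>%
    select("experiment_id", "fov_id", "time_h", "area")
  trt_means <- window_log_means(win, treated, window, right_open = FALSE)

  exp_ids <- sort(unique(fovs$experiment_id))
  ctrl_split <- split(ctrl_areas, ctrl_areas$experiment_id)
  trt_split <- split(trt_means, trt_means$experiment_id)

  one_study <- function(s) {
    per_exp <- vapply(exp_ids, function(eid) {
      ca <- ctrl_split[[eid]]
      cf <- unique(ca$fov_id)
      pick_c <- sample(cf, n_control_fov, replace = TRUE)
      # mean over chosen control FOVs on the linear scale, per frame,
      # then the window mean of log10(control mean)
      cm <- purrr::map(pick_c, function(f) {
        x <- ca[ca$fov_id == f, ]
        x$area[order(x$time_h)]
      })
      ctrl_mat <- do.call(cbind, cm)
      ctrl_log <- log10(rowMeans(ctrl_mat))
      tm <- trt_split[[eid]]
      pick_t <- sample(tm$fov_id, n_treated_fov, replace = TRUE)
      mean(ctrl_log) - mean(tm$m[match(pick_t, tm$fov_id)])
    }, numeric(1))
    study_stats(per_exp, conf = conf) %>% mutate(study = s, .before = 1)
  }
  studies <- purrr::map(seq_len(n_sim), one_study) %>% list_rbind()

  summary <- tibble(
    n_studies = n_sim,
    mean_lr = mean(studies$mean_lr),
    mean_moe = mean(studies$moe),
    median_moe = stats::median(studies$moe),
    mean_lower = mean(studies$lower),
    fraction_significant = mean(studies$significant)
  )
  structure(
    list(studies = studies, summary = summary, window = window,
         design = c(n_exp = length(exp_ids), n_control_fov = n_control_fov,
                    n_treated_fov = n_treated_fov),
         seed = seed),
    class = "bootstrap_validation"
  )
}

#' @export
print.bootstrap_validation <- function(x, ...) {
  cat(sprintf(
    "Bootstrap validation: %d studies, %d experiments, window [%g, %g] h\n",
    x$summary$n_studies, x$design[["n_exp"]], x$window[1], x$window[2]))
  print(x$summary)
  invisible(x)
}

#' @describeIn bootstrap_studies Per-study results, one row per simulated
#'   study.
#' @param x A `bootstrap_validation` object.
#' @param ... Unused.
#' @export
tidy.bootstrap_validation <- function(x, ...) x$studies

#' @describeIn bootstrap_studies One-row summary including
#'   `fraction_significant`.
#' @export
glance.bootstrap_validation <- function(x, ...) x$summary
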