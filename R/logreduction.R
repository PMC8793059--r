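#' Per-FOV log reductions against matched controls
#'
#' For every treated field of view and time point, computes the log reduction
#' `LR = log10(control) - log10(treated)`, where the control value is the
#' arithmetic mean, on the linear area scale, of all control FOVs imaged in
#' the same experiment at the same time. A positive LR means the treatment
#' reduced surface coverage; 1 LR corresponds to a 90% reduction.
#'
#' @param data A measurement tibble (see [read_timelapse_csv()]).
#' @param control,treated Labels in the `condition` column identifying the
#'   control and treated series.
#' @param warn_controls Warn when the number of control FOVs at a matched
#'   (experiment, time) differs from the conventional two.
#' @return A tibble with columns `experiment_id`, `fov_id`, `time_h`, `lr`,
#'   one row per treated FOV x time.
#' @export
#' @examples
#' d <- simulate_paired_study(3, 2, 2, treatment_lr = 1, seed = 1)
#' lr <- compute_lr(d)
#' mean_lr(lr, window = c(3, 4))
compute_lr <- function(data, control = "control", treated = "treated",
                       warn_controls = TRUE) {
  data <- validate_timelapse(data)
  present <- unique(data$condition)
  for (lab in c(control, treated)) {
    if (!lab %in% present) {
      abort(paste0("condition label '", lab, "' not present in data"))
    }
  }

  ctrl <- data %>%
    filter(.data$condition == .env$control) %>%
    group_by(.data$experiment_id, .data$time_h) %>%
    summarise(control_area = mean(.data$area),
              n_control_fov = n(), .groups = "drop")

  trt <- data %>%
    filter(.data$condition == .env$treated) %>%
    select("experiment_id", "fov_id", "time_h", "area")

  joined <- left_join(trt, ctrl, by = c("experiment_id", "time_h"))
  orphan <- joined %>% filter(is.na(.data$control_area))
  if (nrow(orphan) > 0) {
    ex <- orphan %>% distinct(.data$experiment_id, .data$time_h) %>% head(5)
    abort(paste0(
      "no matched control measurement for treated series at: ",
      paste(sprintf("(%s, t=%g)", ex$experiment_id, ex$time_h), collapse = ", "),
      if (nrow(orphan) > 5) " ..." else ""
    ))
  }
  if (warn_controls && any(joined$n_control_fov != 2)) {
    counts <- sort(unique(joined$n_control_fov[joined$n_control_fov != 2]))
    warn(paste0("control FOV count per (experiment, time) is ",
                paste(counts, collapse = "/"),
                " rather than the conventional 2; averaging over all available"))
  }

  joined %>%
    mutate(lr = log10(.data$control_area) - log10(.data$area)) %>%
    select("experiment_id", "fov_id", "time_h", "lr") %>%
    arrange(.data$experiment_id, .data$fov_id, .data$time_h)
}

#' Mean log reduction over a time window
#'
#' Averages log-reduction points falling in a time window. By default each
#' (series, time) point carries equal weight (a pooled mean, appropriate for
#' near-balanced data); `per_series = TRUE` first averages within each
#' treated FOV series and then across series. Interior analysis windows are
#' conventionally right-open and the final window of a study closed; control
#' this with `right_open`.
#'
#' @param lr A log-reduction tibble from [compute_lr()] (columns
#'   `experiment_id`, `fov_id`, `time_h`, `lr`).
#' @param window Numeric length-2 vector `c(t0, t1)` in hours, or `NULL`
#'   for all points.
#' @param right_open If `TRUE`, points at exactly `t1` are excluded.
#' @param per_series Average per series first, then across series.
#' @return A single numeric mean LR.
#' @export
mean_lr <- function(lr, window = NULL, right_open = FALSE,
                    per_series = FALSE) {
  stopifnot(is.data.frame(lr), all(c("time_h", "lr") %in% names(lr)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    keep <- lr$time_h >= window[1] &
      (if (right_open) lr$time_h < window[2] else lr$time_h <= window[2])
    lr <- lr[keep, , drop = FALSE]
  }
  if (nrow(lr) == 0) abort("no log-reduction points fall in the window")
  if (!all(is.finite(lr$lr))) abort("non-finite log-reduction values")
  if (per_series) {
    lr %>%
      group_by(.data$experiment_id, .data$fov_id) %>%
      summarise(lr = mean(.data$lr), .groups = "drop") %>%
      pull(.data$lr) %>%
      mean()
  } else {
    mean(lr$lr)
  }
}

#' Percent reduction implied by a log reduction
#'
#' Documentation helper: `1 - 10^(-LR)` as a percentage (LR 1 = 90%,
#' LR 2 = 99%).
#'
#' @param lr Log reduction (log10 units).
#' @return Percent reduction.
#' @export
percent_reduction <- function(lr) 100 * (1 - 10^(-lr))
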