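#' Quadratic trend of repeatability variance versus log reduction
#'
#' Treatment-efficacy data show a frown-shaped relationship: repeatability
#' variance is small for ineffective and for highly effective treatments and
#' peaks at middling efficacy. This fits the ordinary-least-squares quadratic
#' `variance = a0 + a1 * LR + a2 * LR^2` to (mean LR, repeatability variance)
#' points, optionally weighted (e.g. by the number of FOVs behind each
#' point).
#'
#' @param points A data frame with columns `lr` (mean log reduction) and
#'   `variance` (repeatability variance, squared log10 units). A
#'   `repeatability_sd` column is accepted in place of `variance`.
#' @param weights Optional non-negative weights, one per point.
#' @return An object of class `variance_trend` with the fitted `lm`, the
#'   coefficients and the fitted LR range. Has [tidy()], [glance()],
#'   [autoplot()] and [predict_components()] methods.
#' @export
#' @examples
#' pts <- tibble::tibble(lr = c(0, 0.5, 1, 1.5, 2),
#'                       variance = c(0.02, 0.1, 0.24, 0.3, 0.26))
#' fit_variance_trend(pts)
fit_variance_trend <- function(points, weights = NULL) {
  stopifnot(is.data.frame(points))
  if (!"variance" %in% names(points) && "repeatability_sd" %in% names(points)) {
    points$variance <- points$repeatability_sd^2
  }
  stopifnot(all(c("lr", "variance") %in% names(points)))
  if (nrow(points) < 3) abort("at least 3 (lr, variance) points are required")
  if (length(unique(points$lr)) < 3) {
    abort("at least 3 distinct LR values are required for a quadratic fit")
  }
  fit <- if (is.null(weights)) {
    lm(variance ~ lr + I(lr^2), data = points)
  } else {
    stopifnot(length(weights) == nrow(points), all(weights >= 0))
    points$.w <- weights
    lm(variance ~ lr + I(lr^2), data = points, weights = .w)
  }
  cf <- unname(coef(fit))
  if (any(!is.finite(cf))) abort("quadratic fit is singular")
  structure(
    list(coefficients = setNames(cf, c("a0", "a1", "a2")),
         lr_range = range(points$lr),
         fit = fit, points = as_tibble(points[c("lr", "variance")])),
    class = "variance_trend"
  )
}

#' @export
print.variance_trend <- function(x, ...) {
  cat(sprintf(
    "Quadratic variance trend: v(LR) = %.4g + %.4g LR + %.4g LR^2  (LR in [%.2g, %.2g])\n",
    x$coefficients["a0"], x$coefficients["a1"], x$coefficients["a2"],
    x$lr_range[1], x$lr_range[2]))
  invisible(x)
}

#' @describeIn fit_variance_trend Coefficient table (term, estimate).
#' @param x A `variance_trend` object.
#' @param ... Unused.
#' @export
tidy.variance_trend <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @describeIn fit_variance_trend One-row fit summary.
#' @export
glance.variance_trend <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         n = nrow(x$points),
         lr_min = x$lr_range[1], lr_max = x$lr_range[2])
}

#' Evaluate a variance trend at given log reductions
#'
#' @param object A `variance_trend` object.
#' @param lr Log reductions at which to predict the repeatability variance.
#' @param ... Unused.
#' @return Predicted variances, clipped at 0.
#' @export
predict.variance_trend <- function(object, lr, ...) {
  a <- object$coefficients
  unname(pmax(a[["a0"]] + a[["a1"]] * lr + a[["a2"]] * lr^2, 0))
}

#' Predict variance components for an expected log reduction
#'
#' Looks up the repeatability variance expected at a treatment's anticipated
#' mean LR from a fitted [fit_variance_trend()] and splits it into
#' experiment / FOV / time components using supplied proportions. This is the
#' design-planning step for treatment studies: the expected LR sets both the
#' effect size and (through the trend) the variability.
#'
#' @param trend A `variance_trend` object.
#' @param expected_lr Anticipated mean log reduction.
#' @param proportions Length-3 non-negative proportions
#'   (experiment, FOV, time) summing to ~1. Defaults to equal thirds with a
#'   loud warning — supply proportions from pilot data whenever possible.
#' @param c Inflation factor to store (default 12, the convention for
#'   log-reduction designs when serial correlation is not estimated).
#' @return A one-row variance-components tibble.
#' @export
#' @examples
#' pts <- tibble::tibble(lr = c(0, 1, 2), variance = c(0.01, 0.25, 0.2))
#' tr <- fit_variance_trend(pts)
#' predict_components(tr, expected_lr = 1, proportions = c(0.5, 0.45, 0.05))
predict_components <- function(trend, expected_lr,
                               proportions = NULL, c = 12) {
  stopifnot(inherits(trend, "variance_trend"), length(expected_lr) == 1)
  if (is.null(proportions)) {
    warn(paste0(
      "no variance proportions supplied; defaulting to equal thirds. ",
      "Component splits should come from pilot data."
    ))
    proportions <- rep(1 / 3, 3)
  }
  stopifnot(length(proportions) == 3)
  if (any(proportions < 0)) abort("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 0.01) {
    abort("proportions must sum to ~1")
  }
  if (expected_lr < trend$lr_range[1] || expected_lr > trend$lr_range[2]) {
    warn(sprintf(
      "expected_lr %.3g lies outside the fitted LR range [%.3g, %.3g]; extrapolating",
      expected_lr, trend$lr_range[1], trend$lr_range[2]))
  }
  total <- predict(trend, expected_lr)
  variance_components(
    var_exp = proportions[1] * total,
    var_fov = proportions[2] * total,
    var_time = proportions[3] * total,
    r = NA_real_, c = c,
    provenance = "user_supplied"
  )
}

#' @describeIn fit_variance_trend Points and fitted quadratic.
#' @param object A `variance_trend` object.
#' @export
autoplot.variance_trend <- function(object, ...) {
  grid <- tibble(
    lr = seq(object$lr_range[1], object$lr_range[2], length.out = 200)
  )
  grid$variance <- predict(object, grid$lr)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$lr, y = .data$variance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "Mean log reduction",
                  y = expression(Repeatability~variance~(log[10]^2)),
                  title = "Quadratic trend of repeatability variance vs LR") +
    ggplot2::theme_minimal()
}
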