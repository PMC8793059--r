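test_that("serial correlation matches hand-evaluated oracles", {
  # [1, -1, 1, -1]: numerator -3, denominator 4
  expect_equal(serial_correlation(c(1, -1, 1, -1)), -0.75)
  # [1, 1, 1, 1]: numerator 3, denominator 4
  expect_equal(serial_correlation(c(1, 1, 1, 1)), 0.75)
})

test_that("serial correlation pools within series and never straddles boundaries", {
  two <- tibble::tibble(
    experiment_id = rep(c("e1", "e2"), each = 4),
    fov_id = "f1",
    time_h = rep(1:4, 2),
    resid = c(1, -1, 1, -1, 1, 1, 1, 1)
  )
  # numerators: -3 and 3 cancel; denominator 8
  expect_equal(serial_correlation(two), 0)

  # scale invariance per series set
  expect_equal(serial_correlation(two |> dplyr::mutate(resid = 5 * resid)), 0)
  one <- tibble::tibble(experiment_id = "e", fov_id = "f",
                        time_h = 1:4, resid = c(2, -2, 2, -2))
  expect_equal(serial_correlation(one), -0.75)

  short <- tibble::tibble(experiment_id = "e", fov_id = "f",
                          time_h = 1, resid = 1)
  expect_error(serial_correlation(short), "length >= 2")
})

test_that("serial correlation is near zero for iid noise and recovers AR(1) phi", {
  set.seed(101)
  iid <- tibble::tibble(experiment_id = "e", fov_id = "f",
                        time_h = 1:1e5, resid = rnorm(1e5))
  expect_lt(abs(serial_correlation(iid)), 0.02)

  for (phi in c(0.3, 0.8, 0.9)) {
    set.seed(round(1000 * phi))
    n <- 1e4
    innov <- rnorm(n, 0, sqrt(1 - phi^2))
    e <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                  init = rnorm(1)))
    ser <- tibble::tibble(experiment_id = "e", fov_id = "f",
                          time_h = seq_len(n), resid = e)
    expect_lt(abs(serial_correlation(ser) - phi), 0.05)
  }
})

test_that("inflation factor follows (1 + r) / (1 - r) with its limiting behaviour", {
  expect_equal(round(inflation_factor(0.8751), 1), 15.0)
  expect_equal(round(inflation_factor(0.8313), 1), 10.9)
  expect_equal(round(inflation_factor(0.9129), 1), 22.0)
  expect_equal(inflation_factor(0), 1)
  expect_equal(inflation_factor(0.5), 3)
  expect_error(inflation_factor(1), "strictly inside")
  expect_error(inflation_factor(-1.2), "strictly inside")

  r <- seq(-0.99, 0.99, by = 0.01)
  cc <- inflation_factor(r)
  expect_true(all(diff(cc) > 0))          # strictly increasing
  expect_true(all(cc[r <= 0] <= 1))        # at most 1 for r <= 0
})

test_that("degenerate structures collapse to the right components", {
  # per-experiment offsets only: no FOV or time noise
  d <- simulate_growth(4, 2, duration_h = 1, lag_end_h = 0,
                       sd_exp = 0.3, sd_fov = 0, sd_time = 1e-3, seed = 5)
  fit <- suppressMessages(fit_components(d))
  expect_lt(fit$components$var_fov, 1e-4)
  expect_lt(fit$components$var_time, 1e-4)
  expect_gt(fit$components$var_exp, 0.01)

  # all responses identical: every component is (numerically) zero
  d2 <- simulate_growth(3, 2, duration_h = 1, lag_end_h = 0, lag_slope = 0,
                        exp_slope = 0, sd_exp = 0, sd_fov = 0, sd_time = 0,
                        seed = 6)
  fit2 <- suppressMessages(fit_components(d2))
  expect_lt(fit2$components$var_exp + fit2$components$var_fov +
              fit2$components$var_time, 1e-12)
})

test_that("a single experiment is rejected with guidance", {
  d <- simulate_growth(1, 2, duration_h = 1, seed = 8)
  expect_error(fit_components(d), "inestimable")
})

test_that("REML recovers simulated variance components", {
  # 20 replicates of the 6 x 2 x 20 design at the early-phase SDs;
  # mean recovered SD within 30% of truth for every level
  truth <- c(exp = 0.2433, fov = 0.2023, time = 0.0373)
  ests <- purrr::map(1:20, function(s) {
    d <- simulate_growth(6, 2, duration_h = 1, lag_end_h = 0, phi = 0,
                         frame_interval_h = 1 / 19, seed = 4000 + s)
    glance(fit_components(d))
  }) |> purrr::list_rbind()
  got <- c(exp = mean(sqrt(ests$var_exp)), fov = mean(sqrt(ests$var_fov)),
           time = mean(sqrt(ests$var_time)))
  expect_true(all(abs(got - truth) / truth < 0.30))
})

test_that("moments estimator agrees with REML on balanced data", {
  d <- simulate_growth(6, 3, duration_h = 1, lag_end_h = 0, phi = 0,
                       seed = 77)
  reml <- fit_components(d)$components
  mom <- fit_components(d, method = "moments")$components
  for (v in c("var_exp", "var_fov", "var_time")) {
    expect_equal(mom[[v]], reml[[v]], tolerance = 0.01)
  }
  # ragged design is refused
  d_ragged <- d[-1, ]
  expect_error(fit_components(d_ragged, method = "moments"), "balanced")
})

test_that("fitted residuals expose the simulated serial correlation", {
  d <- simulate_growth(4, 2, duration_h = 4, lag_end_h = 0, phi = 0.8751,
                       sd_time = 0.2, frame_interval_h = 4 / 999, seed = 55)
  fit <- fit_components(d)
  expect_lt(abs(fit$components$r - 0.8751), 0.05)
  expect_equal(fit$components$c,
               inflation_factor(fit$components$r))
})

test_that("tidy and glance summarise a fit in broom style", {
  d <- simulate_growth(3, 2, duration_h = 1, seed = 13)
  fit <- fit_components(d)
  td <- tidy(fit)
  expect_equal(td$level, c("experiment", "fov", "time"))
  expect_equal(td$variance, td$sd^2, tolerance = 1e-12)
  expect_equal(sum(td$proportion), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$repeatability_sd,
               sqrt(gl$var_exp + gl$var_fov + gl$var_time * gl$c),
               tolerance = 1e-12)
})
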