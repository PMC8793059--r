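# A dataset with fixed per-FOV log areas: every control FOV in experiment i
# has area 10^c_i, every treated FOV 10^(c_i - lr); constant over time.
degenerate_paired <- function(n_exp = 3, n_ctrl = 3, n_trt = 3, lr = 1,
                              times = c(3, 3.5, 4)) {
  purrr::map(seq_len(n_exp), function(i) {
    base <- 3 + 0.1 * i
    dplyr::bind_rows(
      tidyr::expand_grid(fov_id = paste0("c", seq_len(n_ctrl)),
                         time_h = times) |>
        dplyr::mutate(condition = "control", area = 10^base),
      tidyr::expand_grid(fov_id = paste0("t", seq_len(n_trt)),
                         time_h = times) |>
        dplyr::mutate(condition = "treated", area = 10^(base - lr))
    ) |>
      dplyr::mutate(experiment_id = paste0("e", i))
  }) |> purrr::list_rbind()
}

test_that("combination counts follow the product rule", {
  d <- degenerate_paired(3, 3, 3)
  expect_equal(n_combinations(d), 729)
  draws <- enumerate_combinations(d)
  expect_equal(length(unique(draws$draw)), 729)
  expect_equal(nrow(draws), 729 * 3)

  d1 <- degenerate_paired(1, 1, 1)
  expect_equal(n_combinations(d1), 1)
  expect_equal(nrow(enumerate_combinations(d1)), 1)

  d23 <- degenerate_paired(2, 2, 3)
  expect_equal(n_combinations(d23), 36)  # (2*3)^2 by the product rule
  expect_equal(length(unique(enumerate_combinations(d23)$draw)), 36)

  # ragged FOV counts cannot be enumerated (but are still countable)
  ragged <- dplyr::bind_rows(
    degenerate_paired(1, 2, 2) |> dplyr::mutate(experiment_id = "e1"),
    degenerate_paired(1, 3, 3) |> dplyr::mutate(experiment_id = "e2")
  )
  expect_equal(n_combinations(ragged), (2 * 3) * (2 * 3))
  expect_error(enumerate_combinations(ragged), "ragged")
})

test_that("draws pair each experiment's own FOVs, uniquely per draw", {
  d <- degenerate_paired(2, 2, 2)
  draws <- enumerate_combinations(d)
  expect_true(all(startsWith(draws$control_fov, "c")))
  expect_true(all(startsWith(draws$treated_fov, "t")))
  per_draw <- draws |> dplyr::count(draw)
  expect_true(all(per_draw$n == 2))
  # all 16 draws are distinct
  key <- draws |>
    dplyr::summarise(
      k = paste(experiment_id, control_fov, treated_fov, collapse = "|"),
      .by = draw)
  expect_equal(length(unique(key$k)), 16)
})

test_that("degenerate data give zero-spread studies with the right verdict", {
  d <- degenerate_paired(3, 3, 3, lr = 1)
  bv <- bootstrap_studies(d, n_sim = 50, window = c(3, 4), seed = 1)
  s <- tidy(bv)
  expect_equal(s$mean_lr, rep(1, 50), tolerance = 1e-12)
  expect_equal(s$sem, rep(0, 50), tolerance = 1e-12)
  expect_equal(s$moe, rep(0, 50), tolerance = 1e-12)
  expect_equal(glance(bv)$fraction_significant, 1)

  d0 <- degenerate_paired(3, 3, 3, lr = 0)
  bv0 <- bootstrap_studies(d0, n_sim = 50, window = c(3, 4), seed = 1)
  expect_equal(glance(bv0)$fraction_significant, 0)
})

test_that("bootstrap mean converges to the enumeration average", {
  d <- simulate_paired_study(3, 3, 3, treatment_lr = 0.8,
                             sd_fov = 0.06, sd_time = 0.085, seed = 42)
  window <- c(3, 4)
  # exact enumeration average of the per-study mean LR: every (control,
  # treated) FOV pair is equally likely, so the average equals the mean over
  # experiments of (mean control log-mean - mean treated window mean)
  win <- d |> dplyr::filter(time_h >= window[1], time_h <= window[2])
  cm <- win |>
    dplyr::filter(condition == "control") |>
    dplyr::summarise(m = mean(log10(area)),
                     .by = c(experiment_id, fov_id)) |>
    dplyr::summarise(m = mean(m), .by = experiment_id)
  tm <- win |>
    dplyr::filter(condition == "treated") |>
    dplyr::summarise(m = mean(log10(area)),
                     .by = c(experiment_id, fov_id)) |>
    dplyr::summarise(m = mean(m), .by = experiment_id)
  exact <- mean(cm$m - tm$m)

  bv <- bootstrap_studies(d, n_sim = 5000, window = window, seed = 7)
  mc_se <- sd(tidy(bv)$mean_lr) / sqrt(5000)
  expect_lt(abs(glance(bv)$mean_lr - exact), 2 * mc_se + 1e-6)
})

test_that("results are invariant to order-preserving relabeling", {
  d <- simulate_paired_study(3, 3, 3, treatment_lr = 0.5, duration_h = 1,
                             seed = 15)
  bv1 <- bootstrap_studies(d, n_sim = 100, window = c(0, 1), seed = 3)
  d2 <- d |>
    dplyr::mutate(experiment_id = sub("exp", "assay", experiment_id),
                  fov_id = sub("^", "w", fov_id))
  bv2 <- bootstrap_studies(d2, n_sim = 100, window = c(0, 1), seed = 3)
  expect_equal(glance(bv2)$fraction_significant,
               glance(bv1)$fraction_significant)
  expect_equal(glance(bv2)$mean_lr, glance(bv1)$mean_lr, tolerance = 1e-12)
})

test_that("one-sided lower limits cover the true mean LR at the nominal rate", {
  mu <- 0.8
  covered <- purrr::map_lgl(1:500, function(s) {
    d <- simulate_paired_study(6, 1, 1, treatment_lr = mu, duration_h = 1,
                               lag_end_h = 0, sd_fov = 0.1, sd_time = 0.05,
                               frame_interval_h = 0.1, seed = 20000 + s)
    bv <- suppressWarnings(
      bootstrap_studies(d, n_sim = 1, window = c(0, 1), seed = 1)
    )
    glance(bv)$mean_lower < mu
  })
  expect_gte(mean(covered), 0.90)
})

test_that("bootstrap input errors are caught", {
  d <- degenerate_paired(2, 2, 2)
  expect_error(bootstrap_studies(d, n_sim = 10, window = c(10, 11), seed = 1),
               "window")
  only_ctrl <- d[d$condition == "control", ]
  expect_error(bootstrap_studies(only_ctrl, n_sim = 2, seed = 1),
               "not present")
})
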