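# Published margin-of-error tables used as reference values in tests.
# Layout: one row per experiment count, column pairs are
# (FOV 1, frames 10), (1, 40), (2, 10), (2, 40), (6, 10), (6, 40).

moe_table_long <- function(rows) {
  purrr::imap(rows, function(vals, n_exp_chr) {
    tibble::tibble(
      n_exp = as.integer(n_exp_chr),
      n_fov = c(1L, 1L, 2L, 2L, 6L, 6L),
      n_time = c(10L, 40L, 10L, 40L, 10L, 40L),
      moe = vals
    )
  }) |> purrr::list_rbind()
}

published_moe_grid <- function(phase) {
  rows <- switch(
    phase,
    lag = list(
      `1` = c(20.0167, 19.9466, 16.2652, 16.2221, 13.1839, 13.1661),
      `2` = c(2.1765, 2.1689, 1.7686, 1.7639, 1.4335, 1.4316),
      `3` = c(0.8211, 0.8182, 0.6672, 0.6654, 0.5408, 0.5401),
      `4` = c(0.5723, 0.5703, 0.4650, 0.4638, 0.3769, 0.3764),
      `5` = c(0.4639, 0.4623, 0.3770, 0.3760, 0.3056, 0.3051),
      `6` = c(0.4016, 0.4002, 0.3264, 0.3255, 0.2645, 0.2642)
    ),
    early = list(
      `1` = c(13.1355, 13.0347, 11.6722, 11.6156, 10.5849, 10.5641),
      `2` = c(1.4283, 1.4173, 1.2692, 1.2630, 1.1509, 1.1487),
      `3` = c(0.5388, 0.5347, 0.4788, 0.4765, 0.4342, 0.4333),
      `4` = c(0.3755, 0.3726, 0.3337, 0.3321, 0.3026, 0.3020),
      `5` = c(0.3044, 0.3021, 0.2705, 0.2692, 0.2453, 0.2448),
      `6` = c(0.2636, 0.2615, 0.2342, 0.2331, 0.2124, 0.2120)
    ),
    late = list(
      `1` = c(8.9894, 8.7664, 7.6221, 7.4911, 6.5540, 6.5035),
      `2` = c(0.9774, 0.9532, 0.8288, 0.8145, 0.7126, 0.7071),
      `3` = c(0.3687, 0.3596, 0.3126, 0.3073, 0.2688, 0.2668),
      `4` = c(0.2570, 0.2506, 0.2179, 0.2142, 0.1874, 0.1859),
      `5` = c(0.2083, 0.2032, 0.1767, 0.1736, 0.1519, 0.1507),
      `6` = c(0.1804, 0.1759, 0.1529, 0.1503, 0.1315, 0.1305)
    ),
    stop("unknown phase")
  )
  moe_table_long(rows)
}

# Design-table block for treatments with expected mean LR = 1; the 10- and
# 40-frame columns coincide, implying a negligible inflated time component.
published_lr1_grid <- function() {
  moe_table_long(list(
    `1` = c(22.1521, 22.1521, 18.9751, 18.9751, 16.5211, 16.5211),
    `2` = c(2.4048, 2.4048, 2.0600, 2.0600, 1.7935, 1.7935),
    `3` = c(0.9086, 0.9086, 0.7783, 0.7783, 0.6777, 0.6777),
    `4` = c(0.6333, 0.6333, 0.5425, 0.5425, 0.4723, 0.4723),
    `5` = c(0.5134, 0.5134, 0.4398, 0.4398, 0.3829, 0.3829),
    `6` = c(0.4445, 0.4445, 0.3807, 0.3807, 0.3315, 0.3315)
  ))
}

# Minimal four-point measurement table used across ingest tests.
tiny_measurements <- function(areas = c(100, 200, 150, 300)) {
  tibble::tibble(
    experiment_id = c("e1", "e1", "e1", "e1"),
    fov_id = c("f1", "f1", "f2", "f2"),
    condition = "control",
    time_h = c(0, 1, 0, 1),
    area = areas
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
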