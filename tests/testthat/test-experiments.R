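test_that("regime comparison reports per-seed, per-block criterion times with errors", {
  rc <- run_regime_comparison(seeds = 1:3, n_blocks = 10L)
  expect_setequal(unique(rc$by_block$model), c("flexible", "forgetful"))
  expect_equal(nrow(rc$by_block), 3 * 2 * 10)
  s <- regime_summary(rc)
  expect_true(all(c("mean_t_crit", "se_t_crit", "n_seeds") %in% names(s)))
  expect_true(all(s$n_seeds == 3))
  expect_true(all(is.finite(s$se_t_crit)))
})

test_that("superposed students solve composed tasks exactly", {
  tc <- tiny_teachers(m = 3, d_in = 24, d_out = 4, seed = 2)
  comp <- compose_teachers(tc, type = "sum")
  expect_equal(comp$m, 3L)
  net <- gated_network(p = 3, d_in = 24, d_out = 4, sigma0 = 0)
  net$weights <- tc$weights
  net$gates <- c(1, 1, 0)
  expect_equal(expected_task_loss(net, comp$weights[[1]]), 0)  # A+B
  expect_gt(expected_task_loss(net, comp$weights[[3]]), 1)     # B+C not matched

  # row-composed task: per-row gate selection reaches zero loss...
  rows <- compose_teachers(tc, pairs = list(c(1, 2)), type = "rows")
  netr <- gated_network(p = 2, d_in = 24, d_out = 4, gate_mode = "per_row",
                        sigma0 = 0)
  netr$weights <- tc$weights[1:2]
  netr$gates <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(expected_task_loss(netr, rows$weights[[1]]), 0)
  # ...but no scalar gating of the pure students can (orthogonal teachers)
  nets <- gated_network(p = 2, d_in = 24, d_out = 4, sigma0 = 0)
  nets$weights <- tc$weights[1:2]
  best <- optim(c(0.5, 0.5), function(cc) {
    nets$gates <- cc
    expected_task_loss(nets, rows$weights[[1]])
  })$value
  expect_gt(best, 0.5)
})

test_that("flexible models compose trained tasks much faster than forgetful ones", {
  comp <- run_task_composition(seeds = 1:2)
  med <- comp$t_crit |>
    dplyr::group_by(seed, model) |>
    dplyr::summarise(med = median(t_crit), .groups = "drop") |>
    tidyr::pivot_wider(names_from = model, values_from = med)
  expect_true(all(med$forgetful / med$flexible > 2))
  # at composed-block ends two gates are on and one is off (which path is
  # off depends on which teacher each path specialized to, so the check is
  # assignment-free), and the gated-off path changes with the composed task
  ge <- comp$gates_end |> dplyr::filter(model == "flexible")
  gates <- as.matrix(ge[, c("gate_1", "gate_2", "gate_3")])
  off_path <- apply(gates, 1, which.min)
  for (i in seq_len(nrow(ge))) {
    g <- sort(gates[i, ])
    expect_lt(g[1], 0.3)        # unmatched path switched off
    expect_gt(g[2], 2 * g[1])   # both matched paths clearly on
  }
  per_seed <- split(data.frame(task = ge$task, off = off_path), ge$seed)
  for (ps in per_seed) {
    offs <- vapply(split(ps$off, ps$task), function(v) v[[1]], numeric(1))
    expect_setequal(offs, 1:3)
  }
})

test_that("per-row gates are required for subtask composition", {
  comp <- run_subtask_composition(seeds = 1:2)
  med <- comp$t_crit |>
    dplyr::group_by(seed, model) |>
    dplyr::summarise(med = median(t_crit), .groups = "drop") |>
    tidyr::pivot_wider(names_from = model, values_from = med)
  expect_true(all(med$forgetful / med$flexible > 2))
})

test_that("phase-diagram bookkeeping: cells, seeds, reproducibility", {
  grid <- run_phase_diagram(block_lengths = c(1, 2),
                            gate_timescales = c(0.05, 0.5),
                            total_time = 8, seeds = 1:2)
  expect_equal(nrow(grid), 2 * 2 * 2)
  g <- glance(grid)
  expect_equal(g$n_cells, 4L)
  expect_equal(g$n_seeds, 2L)
  expect_equal(g$n_failed, 0L)
  grid2 <- run_phase_diagram(block_lengths = c(1, 2),
                             gate_timescales = c(0.05, 0.5),
                             total_time = 8, seeds = 1:2)
  expect_identical(as.data.frame(grid), as.data.frame(grid2))

  # forgetful corner: slow gates stay unspecialized
  slow <- grid |> dplyr::filter(tau_c == 0.5)
  fast <- grid |> dplyr::filter(tau_c == 0.05)
  expect_lt(mean(slow$total_alignment), mean(fast$total_alignment))
})

test_that("switch-trend tables carry one slope per seed and model", {
  st <- run_switch_trend(seeds = 1:2, n_blocks = 20L)
  expect_equal(nrow(st$trends), 4)
  expect_equal(nrow(st$per_block), 2 * 2 * 20)
  st2 <- run_switch_trend(seeds = 1:2, n_blocks = 20L)
  expect_identical(st$trends, st2$trends)
  expect_true(all(st$trends$slope[st$trends$model == "flexible"] < 0))
})
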