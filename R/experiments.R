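# Scripted experiment suites: regime comparison, compositional
# generalization, phase diagrams, switch-speed trends.

fig2_defaults <- function() {
  list(p = 2L, m = 2L, d_in = 32L, d_out = 8L, tau_w = 1.3, tau_c = 0.03,
       lambda_norm = 1, lambda_nonneg = 1, block_length = 1, n_blocks = 30L)
}

seeded_pair <- function(seed, pars, gate_mode = "scalar") {
  teachers <- make_teachers(m = pars$m, d_in = pars$d_in, d_out = pars$d_out,
                            seed = seed)
  net <- gated_network(p = pars$p, d_in = pars$d_in, d_out = pars$d_out,
                       tau_w = pars$tau_w, tau_c = pars$tau_c,
                       lambda_norm = pars$lambda_norm,
                       lambda_nonneg = pars$lambda_nonneg,
                       gate_mode = gate_mode, seed = seed + 10000L)
  list(teachers = teachers, net = net)
}

#' Flexible-vs-forgetful regime comparison
#'
#' Trains, for each seed, a fast-bounded-gate network and its matched
#' forgetful control ([forgetful_baseline()], same initialization) on the
#' same blocked two-task curriculum, and summarizes per-block
#' time-to-criterion, final total alignment, and the regime classification.
#'
#' @param seeds Integer vector of seeds (teachers and initialization vary by
#'   seed; runs are deterministic in expectation mode).
#' @param n_blocks Number of curriculum blocks (default 30).
#' @param threshold Loss criterion for [time_to_criterion()] (default 0.1).
#' @param pars Optional list overriding the default configuration (tau_c =
#'   0.03, tau_w = 1.3, block_length = 1, d_in = 32, d_out = 8, lambda = 1).
#' @return A list of class `gf_regime_comparison` with tibbles `by_block`
#'   (`seed`, `model`, `block`, `t_crit`) and `by_seed` (`seed`, `model`,
#'   `final_alignment`, `regime`).
#' @export
run_regime_comparison <- function(seeds = 1:10, n_blocks = 30L,
                                  threshold = 0.1, pars = list()) {
  pars <- modifyList(fig2_defaults(), c(pars, list(n_blocks = n_blocks)))
  cur <- make_curriculum(n_blocks = pars$n_blocks,
                         block_length = pars$block_length, n_tasks = pars$m)
  res <- purrr::map(seeds, function(seed) {
    sp <- seeded_pair(seed, pars)
    models <- list(flexible = sp$net, forgetful = forgetful_baseline(sp$net))
    purrr::imap(models, function(net, label) {
      traj <- simulate_dynamics(net, sp$teachers, cur)
      tc <- time_to_criterion(traj, threshold)
      list(by_block = dplyr::mutate(tc, seed = seed, model = label,
                                    .before = 1),
           by_seed = tibble::tibble(
             seed = seed, model = label,
             final_alignment = traj$total_alignment[nrow(traj)],
             regime = classify_regime(traj, threshold = threshold)))
    })
  })
  flat <- purrr::flatten(res)
  structure(list(
    by_block = purrr::map_dfr(flat, "by_block"),
    by_seed = purrr::map_dfr(flat, "by_seed"),
    pars = pars, threshold = threshold),
    class = "gf_regime_comparison")
}

#' @export
print.gf_regime_comparison <- function(x, ...) {
  cat("<gf_regime_comparison>\n")
  print(dplyr::count(x$by_seed, .data$model, .data$regime))
  invisible(x)
}

#' Summarize a regime comparison over seeds
#'
#' Mean and standard error of the per-block time-to-criterion across seeds,
#' per model.
#'
#' @param comparison A [run_regime_comparison()] result.
#' @return A tibble with `model`, `block`, `mean_t_crit`, `se_t_crit`,
#'   `n_seeds`.
#' @export
regime_summary <- function(comparison) {
  comparison$by_block |>
    dplyr::group_by(.data$model, .data$block) |>
    dplyr::summarise(mean_t_crit = mean(.data$t_crit),
                     se_t_crit = stats::sd(.data$t_crit) / sqrt(dplyr::n()),
                     n_seeds = dplyr::n(), .groups = "drop")
}

run_composition <- function(seeds, gate_mode, compose_type, n_blocks_train,
                            n_blocks_test, threshold, pars) {
  defaults <- modifyList(fig2_defaults(), list(p = 3L, m = 3L))
  pars <- modifyList(defaults, pars)
  cur1 <- make_curriculum(n_blocks = n_blocks_train,
                          block_length = pars$block_length, n_tasks = 3L)
  cur2 <- make_curriculum(n_blocks = n_blocks_test,
                          block_length = pars$block_length, n_tasks = 3L)
  res <- purrr::map(seeds, function(seed) {
    sp <- seeded_pair(seed, pars, gate_mode = gate_mode)
    composed <- compose_teachers(sp$teachers, type = compose_type)
    models <- list(flexible = sp$net, forgetful = forgetful_baseline(sp$net))
    purrr::imap(models, function(net, label) {
      tr1 <- simulate_dynamics(net, sp$teachers, cur1)
      tr2 <- simulate_dynamics(final_network(tr1), composed, cur2)
      traj <- dplyr::bind_rows(
        dplyr::mutate(tibble::as_tibble(tr1)[, c("time", "block", "task", "loss")],
                      phase = "train"),
        dplyr::mutate(tibble::as_tibble(tr2)[, c("time", "block", "task", "loss")],
                      phase = "compose",
                      time = .data$time + attr(tr1, "curriculum")$total_time,
                      block = .data$block + n_blocks_train))
      gates_end <- if (gate_mode == "scalar") {
        tibble::as_tibble(tr2)[, c("block", "task",
                                   paste0("gate_", seq_len(pars$p)))] |>
          dplyr::group_by(.data$block, .data$task) |>
          dplyr::slice_tail(n = 1) |>
          dplyr::ungroup()
      } else NULL
      list(trajectories = dplyr::mutate(traj, seed = seed, model = label,
                                        .before = 1),
           t_crit = dplyr::mutate(time_to_criterion(tr2, threshold),
                                  seed = seed, model = label, .before = 1),
           gates_end = if (!is.null(gates_end)) {
             dplyr::mutate(gates_end, seed = seed, model = label, .before = 1)
           })
    })
  })
  flat <- purrr::flatten(res)
  structure(list(
    trajectories = purrr::map_dfr(flat, "trajectories"),
    t_crit = purrr::map_dfr(flat, "t_crit"),
    gates_end = purrr::map_dfr(purrr::compact(purrr::map(flat, "gates_end")),
                               identity),
    pars = pars, threshold = threshold, compose_type = compose_type),
    class = "gf_composition")
}

#' @export
print.gf_composition <- function(x, ...) {
  cat(sprintf("<gf_composition> (%s composition)\n", x$compose_type))
  print(x$t_crit |>
          dplyr::group_by(.data$seed, .data$model) |>
          dplyr::summarise(median_t_crit = stats::median(.data$t_crit),
                           .groups = "drop") |>
          tidyr::pivot_wider(names_from = "model",
                             values_from = "median_t_crit"))
  invisible(x)
}

#' Task-composition generalization experiment
#'
#' Phase 1 trains three paths on three teachers A, B, C in alternating
#' blocks; phase 2 switches the curriculum to cycle through the additive
#' compositions A+B, A+C, B+C. In the flexible regime the trained gates
#' recombine the specialized students, so the composed tasks are reached much
#' faster than by the forgetful control, which must re-learn weights.
#'
#' @param seeds Seeds (default 1:5).
#' @param n_blocks_train,n_blocks_test Blocks in the two phases (defaults 18
#'   and 9).
#' @param threshold Loss criterion for phase-2 [time_to_criterion()].
#' @param pars Optional configuration overrides (see
#'   [run_regime_comparison()]).
#' @return A list of class `gf_composition` with tibbles `trajectories`
#'   (`seed`, `model`, `phase`, `time`, `block`, `task`, `loss`), `t_crit`
#'   (phase-2, per block), and `gates_end` (gate values at phase-2 block
#'   ends).
#' @export
run_task_composition <- function(seeds = 1:5, n_blocks_train = 18L,
                                 n_blocks_test = 9L, threshold = 0.1,
                                 pars = list()) {
  run_composition(seeds, "scalar", "sum", n_blocks_train, n_blocks_test,
                  threshold, pars)
}

#' Subtask (row-wise) composition experiment
#'
#' Like [run_task_composition()], but the composed tasks concatenate
#' alternating rows of pairs of teachers, and the model uses per-row gates
#' that can select individual rows of each student.
#'
#' @inheritParams run_task_composition
#' @return A `gf_composition` (without scalar `gates_end`).
#' @export
run_subtask_composition <- function(seeds = 1:5, n_blocks_train = 18L,
                                    n_blocks_test = 9L, threshold = 0.1,
                                    pars = list()) {
  run_composition(seeds, "per_row", "rows", n_blocks_train, n_blocks_test,
                  threshold, pars)
}

#' Specialization phase diagram
#'
#' Seed-averaged final total alignment over a grid of block lengths crossed
#' with either gate timescales (`gate_timescales`, the inverse gate learning
#' rate) or regularization multipliers (`lambda_mults`, scaling both gate
#' penalties). All cells are trained for the same total time, so short-block
#' cells see more switches but the same amount of data.
#'
#' @param block_lengths Block lengths (default: 8 values from `total_time/96`
#'   to `total_time/8`).
#' @param gate_timescales Gate time constants `tau_c` for the second axis
#'   (default: 8 log-spaced values from 0.02 to `tau_w`). Ignored if
#'   `lambda_mults` is given.
#' @param lambda_mults Optional regularization multipliers for the second
#'   axis (applied to both `lambda_norm` and `lambda_nonneg`).
#' @param total_time Total training time per cell (default 48).
#' @param seeds Seeds per cell (default 1:5).
#' @param pars Configuration overrides; defaults use `d_in = 16`,
#'   `d_out = 4`, `tau_w = 1.3`.
#' @return A tibble of class `gf_phase_grid` with one row per cell and seed:
#'   `block_length`, `tau_c` or `lambda_mult`, `seed`, `total_alignment`
#'   (NA if that cell failed). Attribute `"axis2"` names the second axis.
#' @export
run_phase_diagram <- function(block_lengths = NULL, gate_timescales = NULL,
                              lambda_mults = NULL, total_time = 48,
                              seeds = 1:5, pars = list()) {
  defaults <- modifyList(fig2_defaults(), list(d_in = 16L, d_out = 4L))
  pars <- modifyList(defaults, pars)
  block_lengths <- block_lengths %||% (total_time / c(96, 64, 48, 32, 24, 16, 12, 8))
  axis2_name <- if (!is.null(lambda_mults)) "lambda_mult" else "tau_c"
  axis2 <- if (!is.null(lambda_mults)) lambda_mults else
    gate_timescales %||% exp(seq(log(0.02), log(pars$tau_w), length.out = 8))

  grid <- tidyr::expand_grid(block_length = block_lengths, axis2 = axis2,
                             seed = seeds)
  grid$total_alignment <- purrr::pmap_dbl(
    grid, function(block_length, axis2, seed) {
      cell <- pars
      if (axis2_name == "tau_c") {
        cell$tau_c <- axis2
      } else {
        cell$lambda_norm <- pars$lambda_norm * axis2
        cell$lambda_nonneg <- pars$lambda_nonneg * axis2
      }
      n_blocks <- max(1L, as.integer(round(total_time / block_length)))
      tryCatch({
        sp <- seeded_pair(seed, cell)
        cur <- make_curriculum(n_blocks = n_blocks, block_length = block_length,
                               n_tasks = cell$m)
        traj <- simulate_dynamics(sp$net, sp$teachers, cur)
        traj$total_alignment[nrow(traj)]
      }, error = function(e) NA_real_)
    })
  names(grid)[names(grid) == "axis2"] <- axis2_name
  structure(grid, class = c("gf_phase_grid", class(tibble::tibble())),
            axis2 = axis2_name, total_time = total_time,
            n_seeds = length(seeds), pars = pars)
}

#' Monotonicity of specialization in block length
#'
#' Quantifies the claim that, at fixed total training time, specialization
#' grows with block length. Deep inside the flexible region the total
#' alignment saturates at 1 (rank correlations degenerate under ties), so the
#' statistic is computed on the regime-boundary band of the grid: the rows of
#' the second axis whose alignment varies materially across block lengths
#' (range > `band_range`; all rows if none does). Their mean alignment per
#' block length is rank-correlated with block length.
#'
#' @param grid A [run_phase_diagram()] result.
#' @param band_range Minimum alignment range across block lengths for a row
#'   to count as part of the regime boundary (default 0.1).
#' @return A list with `spearman_rho`, the per-block-length `profile` tibble,
#'   and the `band` rows used.
#' @export
block_length_monotonicity <- function(grid, band_range = 0.1) {
  stopifnot(inherits(grid, "gf_phase_grid"))
  axis2 <- attr(grid, "axis2")
  cells <- tidy(grid)
  ranges <- cells |>
    dplyr::group_by(.data[[axis2]]) |>
    dplyr::summarise(range = diff(range(.data$mean_alignment)),
                     .groups = "drop")
  band <- ranges[[axis2]][ranges$range > band_range]
  if (length(band) == 0L) band <- ranges[[axis2]]
  profile <- cells |>
    dplyr::filter(.data[[axis2]] %in% band) |>
    dplyr::group_by(.data$block_length) |>
    dplyr::summarise(mean_alignment = mean(.data$mean_alignment),
                     .groups = "drop")
  rho <- cor(profile$block_length, profile$mean_alignment,
             method = "spearman")
  list(spearman_rho = rho, profile = profile, band = band)
}

#' Post-switch speed trend experiment
#'
#' For each seed, runs the flexible model and its forgetful control on the
#' blocked curriculum and regresses the mean post-switch loss (first fraction
#' of each block) on the block index. Accelerating task switching shows as a
#' negative slope; the forgetful control shows a flat or positive one
#' (deceleration).
#'
#' The default block length is 2 (twice the regime-comparison default): a
#' switching-speed comparison is only well posed when both models re-master
#' the task within every block, as human subjects do in the alternating-task
#' experiments this mirrors, and the forgetful control needs the longer block
#' to converge.
#'
#' @param seeds Seeds (default 1:10).
#' @param n_blocks Blocks per run (default 24; at least 20 recommended).
#' @param window Post-switch window as a fraction of the block (default 0.1).
#' @param pars Configuration overrides (see [run_regime_comparison()]).
#' @return A list of class `gf_switch_trend` with tibbles `trends` (`seed`,
#'   `model`, `slope`, `sign`) and `per_block` (`seed`, `model`, `block`,
#'   `post_switch_loss`).
#' @export
run_switch_trend <- function(seeds = 1:10, n_blocks = 24L, window = 0.1,
                             pars = list()) {
  pars <- modifyList(fig2_defaults(),
                     c(list(block_length = 2), pars, list(n_blocks = n_blocks)))
  cur <- make_curriculum(n_blocks = pars$n_blocks,
                         block_length = pars$block_length, n_tasks = pars$m)
  res <- purrr::map(seeds, function(seed) {
    sp <- seeded_pair(seed, pars)
    models <- list(flexible = sp$net, forgetful = forgetful_baseline(sp$net))
    purrr::imap(models, function(net, label) {
      traj <- simulate_dynamics(net, sp$teachers, cur)
      tr <- switch_speed_trend(traj, window = window)
      list(trends = tibble::tibble(seed = seed, model = label,
                                   slope = tr$slope, sign = tr$sign),
           per_block = dplyr::mutate(tr$per_block, seed = seed, model = label,
                                     .before = 1))
    })
  })
  flat <- purrr::flatten(res)
  structure(list(trends = purrr::map_dfr(flat, "trends"),
                 per_block = purrr::map_dfr(flat, "per_block"),
                 pars = pars, window = window),
            class = "gf_switch_trend")
}

#' @export
print.gf_switch_trend <- function(x, ...) {
  cat("<gf_switch_trend>\n")
  print(x$trends |>
          dplyr::group_by(.data$model) |>
          dplyr::summarise(mean_slope = mean(.data$slope),
                           n_negative = sum(.data$slope < 0),
                           n_seeds = dplyr::n()))
  invisible(x)
}
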