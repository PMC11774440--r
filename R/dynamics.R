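# Integration of the coupled weight/gate gradient flow over a curriculum.

#' Integrate the gated-network gradient flow over a blocked curriculum
#'
#' Explicit-Euler integration of the coupled flow
#' `tau_w dW_p/dt = -grad_{W_p} L`, `tau_c dc_p/dt = -grad_{c_p} L`
#' with the active teacher switching according to the curriculum. In
#' expectation mode the exact input-averaged gradients are used, so the
#' trajectory is deterministic given the initialization; in minibatch mode a
#' fresh Gaussian batch is sampled at every step (seeded by
#' `curriculum$seed`). The recorded loss is always the closed-form expected
#' task loss, so timing metrics are free of sampling jitter.
#'
#' `dt` is snapped to an integer divisor of the block length so that block
#' boundaries coincide with integration steps; it must not exceed `tau_c / 10`
#' (explicit Euler stability guard for the fast gate flow).
#'
#' @param net A [gated_network()]; its current weights/gates are the initial
#'   condition, so simulations can be chained across curricula.
#' @param teachers A [make_teachers()] set with dimensions matching `net`.
#' @param curriculum A [make_curriculum()].
#' @param dt Integration step; default `tau_c / 50`.
#' @param record_every Record every this many steps (default: about 50 records
#'   per block).
#' @return A `gf_trajectory`: a tibble with one row per recorded step and
#'   columns `time`, `block`, `task`, `loss`, per-path gates (`gate_*`; row
#'   means in per-row mode), per-path weight norms (`wnorm_*`), per-pair
#'   student/teacher row-mean cosines (`align_p<q>_t<m>`), `total_alignment`,
#'   and instantaneous update-rate norms `dw_norm`, `dc_norm`. The final
#'   network is attached as attribute `"network"`.
#' @examples
#' tc <- make_teachers(m = 2, d_in = 16, d_out = 4, seed = 1)
#' net <- gated_network(p = 2, d_in = 16, d_out = 4, tau_c = 0.1, seed = 1)
#' traj <- simulate_dynamics(net, tc, make_curriculum(n_blocks = 4), dt = 0.01)
#' glance(traj)
#' @export
simulate_dynamics <- function(net, teachers, curriculum, dt = net$tau_c / 50,
                              record_every = NULL) {
  stopifnot(inherits(net, "gf_network"), inherits(teachers, "gf_teachers"),
            inherits(curriculum, "gf_curriculum"))
  if (net$d_in != teachers$d_in || net$d_out != teachers$d_out) {
    abort("network and teachers disagree on dimensions", class = "gf_dim_error")
  }
  if (max(curriculum$task_order) > teachers$m) {
    abort("curriculum task_order references a task beyond the teacher set",
          class = "gf_invalid_config")
  }
  if (dt > net$tau_c / 10 + 1e-12) {
    abort(sprintf("dt = %g exceeds the stability guard tau_c / 10 = %g",
                  dt, net$tau_c / 10), class = "gf_invalid_config")
  }

  if (curriculum$n_blocks == 0L) {
    return(new_trajectory(empty_trajectory_tbl(net, teachers), net, curriculum,
                          dt, 1L, teachers))
  }

  steps_per_block <- max(1L, as.integer(round(curriculum$block_length / dt)))
  dt_eff <- curriculum$block_length / steps_per_block
  record_every <- record_every %||% max(1L, steps_per_block %/% 50L)
  record_every <- as.integer(record_every)

  ord <- curriculum$task_order
  block_tasks <- ord[((seq_len(curriculum$n_blocks) - 1L) %% length(ord)) + 1L]
  task_per_step <- rep(block_tasks - 1L, each = steps_per_block)

  wstar <- array(unlist(teachers$weights),
                 dim = c(teachers$d_out, teachers$d_in, teachers$m))
  w0 <- array(unlist(net$weights), dim = c(net$d_out, net$d_in, net$p))
  c0 <- gate_matrix(net)

  run <- function() {
    cpp_integrate_gated(
      w0, c0, wstar, task_per_step, dt_eff, net$tau_w, net$tau_c,
      net$lambda_norm, net$lambda_nonneg, net$norm_order,
      net$gate_mode == "per_row", record_every, steps_per_block,
      curriculum$sampling == "minibatch", curriculum$batch_size)
  }
  res <- if (curriculum$sampling == "minibatch" && !is.null(curriculum$seed)) {
    withr::with_seed(curriculum$seed, run())
  } else {
    run()
  }

  p <- net$p
  m <- teachers$m
  gates <- res$gates
  colnames(gates) <- paste0("gate_", seq_len(p))
  wnorm <- res$w_norm
  colnames(wnorm) <- paste0("wnorm_", seq_len(p))
  align <- res$align
  colnames(align) <- paste0("align_p", rep(seq_len(p), each = m),
                            "_t", rep(seq_len(m), times = p))

  tbl <- dplyr::bind_cols(
    tibble::tibble(time = as.numeric(res$time),
                   block = as.integer(res$block),
                   task = as.integer(res$task),
                   loss = as.numeric(res$loss)),
    tibble::as_tibble(gates), tibble::as_tibble(wnorm),
    tibble::as_tibble(align),
    tibble::tibble(total_alignment = as.numeric(res$total_align),
                   dw_norm = as.numeric(res$dw_norm),
                   dc_norm = as.numeric(res$dc_norm)))

  net_out <- net
  net_out$weights <- lapply(seq_len(p), function(q) res$W_final[, , q, drop = TRUE])
  if (net$d_out == 1L) {
    net_out$weights <- lapply(net_out$weights, function(w) matrix(w, nrow = 1))
  }
  net_out$gates <- if (net$gate_mode == "scalar") drop(res$C_final) else res$C_final
  new_trajectory(tbl, net_out, curriculum, dt_eff, record_every, teachers)
}

empty_trajectory_tbl <- function(net, teachers) {
  p <- net$p
  m <- teachers$m
  nm <- c("time", "block", "task", "loss", paste0("gate_", seq_len(p)),
          paste0("wnorm_", seq_len(p)),
          paste0("align_p", rep(seq_len(p), each = m), "_t",
                 rep(seq_len(m), times = p)),
          "total_alignment", "dw_norm", "dc_norm")
  tbl <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(nm)), nm))
  tbl$block <- integer(0)
  tbl$task <- integer(0)
  tbl
}

new_trajectory <- function(tbl, network, curriculum, dt, record_every,
                           teachers = NULL) {
  structure(tbl,
            class = c("gf_trajectory", class(tibble::tibble())),
            network = network, curriculum = curriculum, dt = dt,
            record_every = record_every, teachers = teachers)
}

#' Coerce a data frame to a trajectory
#'
#' Mainly useful for building hand-crafted trajectories (e.g. synthetic loss
#' curves) to feed the metric functions. The data frame needs at least `time`,
#' `block` and `loss` columns.
#'
#' @param x A data frame.
#' @param block_length Block duration associated with the trajectory.
#' @return A `gf_trajectory`.
#' @export
as_trajectory <- function(x, block_length = 1) {
  stopifnot(all(c("time", "block", "loss") %in% names(x)))
  cur <- make_curriculum(n_blocks = max(c(0L, x$block)),
                         block_length = block_length,
                         n_tasks = max(c(1L, x$task)))
  new_trajectory(tibble::as_tibble(x), NULL, cur, NA_real_, NA_integer_)
}

#' Final network state of a simulation
#'
#' @param traj A `gf_trajectory` (or deep-network trajectory).
#' @return The network object at the end of the run.
#' @export
final_network <- function(traj) {
  attr(traj, "network")
}
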