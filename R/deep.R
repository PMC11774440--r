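# Two-layer fully-connected linear network with a fast, regularized second
# layer, and the sorting analysis that extracts emergent students and gates.

#' Construct a two-layer fully-connected linear network
#'
#' A deep-linear generalization with no built-in pathway structure:
#' `y = W2 W1 x` with hidden width `hidden`. The second layer learns on a
#' faster timescale (`tau_2 < tau_1`) and carries the gate-style
#' regularization (per output row `i`: `0.5 * (||W2[i, ]||_1 - 1)^2` plus the
#' elementwise nonnegativity hinge) -- its entries play the role of gates.
#' Under a blocked curriculum the first layer then self-organizes into
#' task-specialized row groups and the second layer into emergent gates that
#' switch them.
#'
#' `W1` is initialized i.i.d. Gaussian with sd `sigma0 / sqrt(d_in)` (small,
#' as in the shallow model); `W2` with sd `1 / sqrt(hidden)` so the fast
#' layer starts at unit scale and can immediately route learning signal to
#' the first layer.
#'
#' @param d_in,d_out Input/output dimensions.
#' @param hidden Hidden width (default `2 * d_out`, room for two specialized
#'   sub-students).
#' @param tau_1,tau_2 Layer time constants; `tau_2 < tau_1` required.
#' @param lambda_norm,lambda_nonneg Regularization weights on the second
#'   layer.
#' @param norm_order Norm for the bounding penalty (1 or 2).
#' @param sigma0 First-layer initialization scale.
#' @param seed Optional initialization seed.
#' @return An object of class `gf_deep_network`.
#' @export
deep_network <- function(d_in = 32, d_out = 8, hidden = 2 * d_out,
                         tau_1 = 1.3, tau_2 = 0.03, lambda_norm = 1,
                         lambda_nonneg = 1, norm_order = 1, sigma0 = 0.01,
                         seed = NULL) {
  stopifnot(d_in >= 1, d_out >= 1, hidden >= 1, tau_1 > 0, tau_2 > 0,
            lambda_norm >= 0, lambda_nonneg >= 0, norm_order %in% c(1, 2))
  if (tau_2 > tau_1) {
    abort("tau_2 must not exceed tau_1 (the second layer is the fast one)",
          class = "gf_invalid_config")
  }
  draw <- function() {
    list(W1 = matrix(rnorm(hidden * d_in, sd = sigma0 / sqrt(d_in)), hidden, d_in),
         W2 = matrix(rnorm(d_out * hidden, sd = 1 / sqrt(hidden)), d_out, hidden))
  }
  ws <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(W1 = ws$W1, W2 = ws$W2, d_in = as.integer(d_in),
         d_out = as.integer(d_out), hidden = as.integer(hidden),
         tau_1 = tau_1, tau_2 = tau_2, lambda_norm = lambda_norm,
         lambda_nonneg = lambda_nonneg, norm_order = as.integer(norm_order),
         sigma0 = sigma0, seed = seed),
    class = "gf_deep_network")
}

#' @export
print.gf_deep_network <- function(x, ...) {
  cat(sprintf(
    "<gf_deep_network> %d -> %d -> %d, tau_1 %g, tau_2 %g, lambda (%g, %g)\n",
    x$d_in, x$hidden, x$d_out, x$tau_1, x$tau_2, x$lambda_norm,
    x$lambda_nonneg))
  invisible(x)
}

#' Forward pass of the deep linear network
#'
#' @param object A [deep_network()].
#' @param x Input vector or `d_in` x `n` matrix.
#' @param ... Unused.
#' @return Output vector or matrix `y = W2 W1 x`.
#' @export
predict.gf_deep_network <- function(object, x, ...) {
  x <- as.matrix(x)
  if (nrow(x) != object$d_in) {
    abort(sprintf("input has %d rows; expected d_in = %d", nrow(x),
                  object$d_in), class = "gf_dim_error")
  }
  y <- object$W2 %*% (object$W1 %*% x)
  if (ncol(y) == 1L) drop(y) else y
}

#' Integrate the deep-linear gradient flow over a blocked curriculum
#'
#' Explicit-Euler flow with per-layer timescales: `tau_1 dW1/dt = W2' E`,
#' `tau_2 dW2/dt = E W1' - reg(W2)`, with `E` the expected error matrix of
#' the active teacher and the gate-style regularizer applied to the second
#' layer only. Records the expected task loss and layer-wise update-rate
#' norms, and keeps end-of-block snapshots of both layers for the sorting
#' analysis.
#'
#' @param net A [deep_network()].
#' @param teachers A [make_teachers()] set.
#' @param curriculum A [make_curriculum()] (expectation mode).
#' @param dt Step; default `tau_2 / 50`, must not exceed `tau_2 / 10`.
#' @param record_every Record every this many steps.
#' @return A `gf_deep_trajectory` tibble with columns `time`, `block`,
#'   `task`, `loss`, `dw1_norm`, `dw2_norm`. The final network is attribute
#'   `"network"`; end-of-block snapshots are attribute `"block_end"` (lists
#'   of `W1`/`W2` per block).
#' @export
simulate_deep <- function(net, teachers, curriculum, dt = net$tau_2 / 50,
                          record_every = NULL) {
  stopifnot(inherits(net, "gf_deep_network"), inherits(teachers, "gf_teachers"),
            inherits(curriculum, "gf_curriculum"))
  if (net$d_in != teachers$d_in || net$d_out != teachers$d_out) {
    abort("network and teachers disagree on dimensions", class = "gf_dim_error")
  }
  if (dt > net$tau_2 / 10 + 1e-12) {
    abort(sprintf("dt = %g exceeds the stability guard tau_2 / 10 = %g",
                  dt, net$tau_2 / 10), class = "gf_invalid_config")
  }
  if (curriculum$n_blocks == 0L) {
    tbl <- tibble::tibble(time = numeric(0), block = integer(0),
                          task = integer(0), loss = numeric(0),
                          dw1_norm = numeric(0), dw2_norm = numeric(0))
    return(structure(tbl, class = c("gf_deep_trajectory", class(tibble::tibble())),
                     network = net, curriculum = curriculum, dt = dt,
                     block_end = list()))
  }

  steps_per_block <- max(1L, as.integer(round(curriculum$block_length / dt)))
  dt_eff <- curriculum$block_length / steps_per_block
  record_every <- record_every %||% max(1L, steps_per_block %/% 50L)

  ord <- curriculum$task_order
  block_tasks <- ord[((seq_len(curriculum$n_blocks) - 1L) %% length(ord)) + 1L]
  task_per_step <- rep(block_tasks - 1L, each = steps_per_block)
  wstar <- array(unlist(teachers$weights),
                 dim = c(teachers$d_out, teachers$d_in, teachers$m))

  res <- cpp_integrate_deep(net$W1, net$W2, wstar, task_per_step, dt_eff,
                            net$tau_1, net$tau_2, net$lambda_norm,
                            net$lambda_nonneg, net$norm_order,
                            as.integer(record_every), steps_per_block)

  tbl <- tibble::tibble(time = as.numeric(res$time),
                        block = as.integer(res$block),
                        task = as.integer(res$task),
                        loss = as.numeric(res$loss),
                        dw1_norm = as.numeric(res$dw1_norm),
                        dw2_norm = as.numeric(res$dw2_norm))
  net_out <- net
  net_out$W1 <- res$W1_final
  net_out$W2 <- res$W2_final
  block_end <- lapply(seq_len(curriculum$n_blocks), function(b) {
    list(W1 = res$W1_block_end[, , b, drop = TRUE],
         W2 = res$W2_block_end[, , b, drop = TRUE])
  })
  structure(tbl, class = c("gf_deep_trajectory", class(tibble::tibble())),
            network = net_out, curriculum = curriculum, dt = dt_eff,
            block_end = block_end, teachers = teachers)
}

#' Sort a deep network into emergent students and gates
#'
#' Assigns each hidden unit to the teacher whose best-matching row maximizes
#' the absolute cosine with that unit's first-layer row (ties broken by the
#' lowest teacher index), permutes the first-layer rows into contiguous
#' teacher groups, applies the same permutation to the second-layer columns,
#' and reads out one emergent gate per group as the mean of its second-layer
#' block. Sorting is a pure relabeling: the input-output map is unchanged.
#'
#' @param net A [deep_network()] (trained or not), or a list with `W1`, `W2`.
#' @param teachers A [make_teachers()] set.
#' @return A list of class `gf_sorting`: `assignment` (teacher index per
#'   hidden unit, original order), `perm` (the applied permutation),
#'   `sorted_W1`, `sorted_W2`, `gates` (length `m`), and
#'   `student_alignment` (per group, the mean over its hidden units of the
#'   best absolute cosine between the unit's first-layer row and the rows of
#'   the assigned teacher -- the first-layer specialization measure; 0 for an
#'   empty group).
#' @export
sort_network <- function(net, teachers) {
  stopifnot(inherits(teachers, "gf_teachers"))
  W1 <- net$W1
  W2 <- net$W2
  m <- teachers$m
  hidden <- nrow(W1)
  score <- matrix(0, hidden, m)
  for (k in seq_len(m)) {
    tk <- teachers$weights[[k]]
    tn <- sqrt(rowSums(tk^2))
    for (j in seq_len(hidden)) {
      rj <- W1[j, ]
      nj <- sqrt(sum(rj^2))
      score[j, k] <- if (nj == 0) 0 else
        max(abs((tk %*% rj) / (tn * nj)))
    }
  }
  assignment <- apply(score, 1, which.max)  # ties -> lowest teacher index
  perm <- order(assignment, seq_len(hidden))
  groups <- split(seq_len(hidden), factor(assignment, levels = seq_len(m)))
  gates <- vapply(groups, function(idx) {
    if (length(idx) == 0L) 0 else mean(W2[, idx, drop = FALSE])
  }, numeric(1))
  student_alignment <- vapply(seq_len(m), function(k) {
    idx <- groups[[k]]
    if (length(idx) == 0L) return(0)
    mean(score[idx, k])
  }, numeric(1))
  structure(list(assignment = as.integer(assignment), perm = perm,
                 sorted_W1 = W1[perm, , drop = FALSE],
                 sorted_W2 = W2[, perm, drop = FALSE],
                 gates = unname(gates),
                 student_alignment = student_alignment,
                 groups = groups),
            class = "gf_sorting")
}

#' Mass concentration of the second layer on the task-matched block
#'
#' For a sorted network, the ratio of the mean absolute second-layer weight
#' in the columns assigned to `active` over the mean in all other columns.
#' Ratios well above 1 indicate gating concentrated on the active task's
#' student (the block-diagonal structure visible at block ends in the
#' flexible regime).
#'
#' @param sorting A [sort_network()] result.
#' @param active Active task index.
#' @return A positive scalar (``Inf`` if the off-block mass is zero).
#' @export
gate_block_mass <- function(sorting, active) {
  stopifnot(inherits(sorting, "gf_sorting"))
  W2 <- sorting$sorted_W2
  in_block <- sorting$assignment[sorting$perm] == active
  on <- mean(abs(W2[, in_block, drop = FALSE]))
  off <- mean(abs(W2[, !in_block, drop = FALSE]))
  if (off == 0) Inf else on / off
}
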