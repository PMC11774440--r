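# Exact reduction of the learning dynamics to the singular-value space of the
# teachers, specialization coordinates, and the closed-form symmetric solution.

#' Project a gated network into the teachers' singular-value space
#'
#' For each pair of singular modes `a` of the two teachers, the student
#' matrices reduce to scalars `w[p, m, a] = u_star_m[, a]' W_p v_star_m[, a]`.
#' Together with the gates, these scalars carry the entire expectation-mode
#' learning dynamics when the students lie in the span of the teacher singular
#' subspaces. Specialization coordinates are derived from them: `w_bar1 =
#' w[1,1] - w[2,1]`, `w_bar2 = w[2,2] - w[1,2]`, `w_bar = (w_bar1 + w_bar2)/2`
#' and the gate separation `c_bar = c_1 - c_2` (mode-averaged).
#'
#' @param net A [gated_network()] with scalar gates.
#' @param teachers A [make_teachers()] set; the reduction is defined for
#'   exactly two mutually orthogonal teachers.
#' @return An object of class `gf_reduced`: list with `w` (`p` x 2 x modes
#'   array), `c` (gates), and `coords` (one-row tibble with `w_bar1`,
#'   `w_bar2`, `w_bar`, `c_bar`).
#' @export
project_network <- function(net, teachers) {
  stopifnot(inherits(net, "gf_network"), inherits(teachers, "gf_teachers"))
  if (teachers$m != 2L) {
    abort("the reduction is defined for exactly M = 2 teachers",
          class = "gf_unsupported_config")
  }
  if (net$gate_mode != "scalar") {
    abort("the reduction is defined for scalar gates",
          class = "gf_unsupported_config")
  }
  a_modes <- length(teachers$svd[[1]]$d)
  w <- array(0, dim = c(net$p, 2L, a_modes))
  for (q in seq_len(net$p)) {
    for (m in 1:2) {
      sv <- teachers$svd[[m]]
      for (a in seq_len(a_modes)) {
        w[q, m, a] <- drop(crossprod(sv$u[, a], net$weights[[q]] %*% sv$v[, a]))
      }
    }
  }
  new_reduced(w, net$gates)
}

new_reduced <- function(w, c) {
  if (is.matrix(w)) w <- array(w, dim = c(dim(w), 1L))
  structure(list(w = w, c = as.numeric(c), coords = reduced_coords(w, c)),
            class = "gf_reduced")
}

reduced_coords <- function(w, c) {
  stopifnot(dim(w)[1] >= 2, dim(w)[2] == 2)
  w_bar1 <- mean(w[1, 1, ] - w[2, 1, ])
  w_bar2 <- mean(w[2, 2, ] - w[1, 2, ])
  tibble::tibble(w_bar1 = w_bar1, w_bar2 = w_bar2,
                 w_bar = (w_bar1 + w_bar2) / 2, c_bar = unname(c[1] - c[2]))
}

#' @export
print.gf_reduced <- function(x, ...) {
  d <- dim(x$w)
  cat(sprintf("<gf_reduced> %d path(s), %d teacher modes x %d SVD mode(s)\n",
              d[1], d[2], d[3]))
  print(x$coords)
  invisible(x)
}

#' Build a full network from reduced coordinates
#'
#' Places each student exactly inside the teachers' singular subspaces:
#' `W_p = sum_{m,a} w[p, m, a] u_star_m[, a] v_star_m[, a]'`. Projecting the
#' result with [project_network()] recovers `w` exactly, which makes this the
#' canonical initial condition for comparing full and reduced dynamics.
#'
#' @param w `p` x 2 matrix (single mode) or `p` x 2 x modes array of reduced
#'   weights.
#' @param gates Length-`p` gate vector.
#' @param teachers A two-teacher [make_teachers()] set.
#' @param ... Hyperparameters passed on to [gated_network()].
#' @return A `gf_network`.
#' @export
network_from_reduced <- function(w, gates, teachers, ...) {
  stopifnot(inherits(teachers, "gf_teachers"), teachers$m == 2L)
  if (is.matrix(w)) w <- array(w, dim = c(dim(w), 1L))
  p <- dim(w)[1]
  net <- gated_network(p = p, d_in = teachers$d_in, d_out = teachers$d_out,
                       sigma0 = 0, ...)
  net$weights <- lapply(seq_len(p), function(q) {
    acc <- matrix(0, teachers$d_out, teachers$d_in)
    for (m in 1:2) {
      sv <- teachers$svd[[m]]
      for (a in seq_len(dim(w)[3])) {
        acc <- acc + w[q, m, a] * tcrossprod(sv$u[, a], sv$v[, a])
      }
    }
    acc
  })
  net$gates <- as.numeric(gates)
  net
}

reduced_eps <- function(w, c, target) {
  a_modes <- dim(w)[3]
  eps <- matrix(0, 2, a_modes)
  for (m in 1:2) {
    eps[m, ] <- as.numeric(m == target) -
      colSums(matrix(c * w[, m, ], nrow = length(c)))
  }
  eps
}

#' Time derivatives of the reduced dynamics
#'
#' The reduced gradient flow under the active teacher `target` (teachers have
#' unit singular values): with the reduced error `eps[m] = 1{m == target} -
#' sum_p c_p w[p, m]` per mode,
#' `dw[p, m]/dt = c_p eps[m] / tau_w` and
#' `dc_p/dt = (sum_m w[p, m] eps[m] - reg_p) / tau_c`,
#' where `reg_p` is the gradient of the weighted gate regularizers.
#'
#' @param rs A `gf_reduced` state.
#' @param target Active teacher index (1 or 2).
#' @param tau_w,tau_c Time constants.
#' @param lambda_norm,lambda_nonneg,norm_order Gate regularization settings.
#' @return List with `dw` (array like `rs$w`), `dc` (vector), `eps`
#'   (2 x modes matrix of teacher-basis error components).
#' @export
reduced_rhs <- function(rs, target, tau_w = 1, tau_c = 1, lambda_norm = 0,
                        lambda_nonneg = 0, norm_order = 1) {
  stopifnot(inherits(rs, "gf_reduced"), target %in% 1:2)
  w <- rs$w
  c <- rs$c
  eps <- reduced_eps(w, c, target)
  dw <- array(0, dim(w))
  for (m in 1:2) dw[, m, ] <- outer(c, eps[m, ]) / tau_w
  task <- vapply(seq_along(c), function(q) sum(w[q, , ] * eps), numeric(1))
  reg <- gate_reg_grad_r(c, lambda_norm, lambda_nonneg, norm_order)
  list(dw = dw, dc = (task - reg) / tau_c, eps = eps)
}

#' Decompose the gate update into its driving terms
#'
#' Splits `tau_c dc_p/dt` into the two teacher-error terms and the
#' regularization term: `eps_1 w_p'w_star_1 + eps_2 w_p'w_star_2 - reg_p`.
#' The error terms scale with both the alignment and the magnitude of the
#' student in teacher space, which is why small initialization attenuates gate
#' changes and specialized students accelerate them.
#'
#' @inheritParams reduced_rhs
#' @return A tibble with one row per path: `path`, `term_teacher1`,
#'   `term_teacher2`, `reg_term`; rows sum to `tau_c * dc_p`.
#' @export
gate_decomposition <- function(rs, target, tau_w = 1, tau_c = 1,
                               lambda_norm = 0, lambda_nonneg = 0,
                               norm_order = 1) {
  stopifnot(inherits(rs, "gf_reduced"), target %in% 1:2)
  eps <- reduced_eps(rs$w, rs$c, target)
  p <- length(rs$c)
  t1 <- vapply(seq_len(p), function(q) sum(rs$w[q, 1, ] * eps[1, ]), numeric(1))
  t2 <- vapply(seq_len(p), function(q) sum(rs$w[q, 2, ] * eps[2, ]), numeric(1))
  reg <- gate_reg_grad_r(rs$c, lambda_norm, lambda_nonneg, norm_order)
  tibble::tibble(path = seq_len(p), term_teacher1 = t1, term_teacher2 = t2,
                 reg_term = -reg)
}

#' Time derivatives of the specialization coordinates
#'
#' The specialization subspace obeys (per mode, reported mode-averaged; gate
#' regularization cancels between the two paths for positive gates under the
#' L1 bound): `tau_c dc_bar/dt = w_bar1 eps_1 - w_bar2 eps_2` and
#' `tau_w dw_bar/dt = c_bar (eps_1 - eps_2) / 2`.
#'
#' @inheritParams reduced_rhs
#' @return One-row tibble with `dw_bar` and `dc_bar`.
#' @export
specialization_rhs <- function(rs, target, tau_w = 1, tau_c = 1) {
  stopifnot(inherits(rs, "gf_reduced"), length(rs$c) == 2L)
  eps <- reduced_eps(rs$w, rs$c, target)
  w <- rs$w
  dc_bar <- sum((w[1, 1, ] - w[2, 1, ]) * eps[1, ] -
                  (w[2, 2, ] - w[1, 2, ]) * eps[2, ]) / tau_c
  c_bar <- rs$c[1] - rs$c[2]
  dw_bar <- mean(c_bar * (eps[1, ] - eps[2, ])) / (2 * tau_w)
  tibble::tibble(dw_bar = dw_bar, dc_bar = dc_bar)
}

#' Closed-form symmetric specialization solution
#'
#' Along a symmetric adaptation trajectory (`w_bar1 = w_bar2 = w_bar`, strong
#' L1 bounding so the gates stay on the simplex `sum_p c_p = 1`), the ratio of
#' the two specialization flows gives the separable ODE
#' `(tau_c / tau_w) dc_bar/dw_bar = 2 w_bar / c_bar`. Integrating from the
#' fully specialized, fully separated state `(c_bar, w_bar) = (1, 1)` yields
#' the first integral `w_bar^2 - (tau_c / (2 tau_w)) c_bar^2 = const`, i.e.
#'
#' `w_bar(c_bar) = sqrt(1 - (tau_c / (2 tau_w)) (1 - c_bar^2))`.
#'
#' The specialization lost while the gates traverse from one task to the other
#' is bounded by `tau_c / (2 tau_w)`: fast gates (small `tau_c / tau_w`)
#' protect the specialized weights.
#'
#' @param c_bar Gate separation value(s) in `[-1, 1]`.
#' @param tau_c,tau_w Time constants.
#' @return `w_bar` value(s).
#' @export
exact_symmetric_solution <- function(c_bar, tau_c, tau_w = 1) {
  stopifnot(tau_c > 0, tau_w > 0)
  if (any(abs(c_bar) > 1 + 1e-12)) {
    abort("c_bar must lie in [-1, 1]", class = "gf_domain_error")
  }
  rad <- 1 - (tau_c / (2 * tau_w)) * (1 - pmin(c_bar, 1)^2)
  if (any(rad < -1e-12)) {
    abort("specialization lost: 1 - (tau_c/2tau_w)(1 - c_bar^2) is negative",
          class = "gf_domain_error")
  }
  sqrt(pmax(rad, 0))
}

#' Integrate the reduced dynamics
#'
#' Integrates the reduced gradient flow of [reduced_rhs()] over a blocked
#' schedule of target teachers. Two integrators are available: `"lsoda"`
#' (adaptive, via \pkg{deSolve}; the accurate default for theory work) and
#' `"euler"` (fixed-step explicit Euler, matching the discretization of
#' [simulate_dynamics()] exactly, for full-vs-reduced comparisons).
#' `constrain_sum = TRUE` replaces the gate regularizers by the exact
#' constraint `sum_p c_p = 1` (the strong-L1 limit): gate updates are
#' projected onto the simplex tangent.
#'
#' @param w0 Initial reduced weights (`p` x 2 matrix or `p` x 2 x modes
#'   array).
#' @param c0 Initial gates (length `p`).
#' @param targets Vector of target teacher indices, one per block.
#' @param block_length Duration of each block.
#' @param tau_w,tau_c,lambda_norm,lambda_nonneg,norm_order Flow parameters.
#' @param dt Step (euler) / output resolution (lsoda); default `tau_c / 50`.
#' @param method `"lsoda"` or `"euler"`.
#' @param constrain_sum Enforce `sum_p c_p = 1` exactly instead of using the
#'   regularizers.
#' @param record_every Record every this many Euler steps (euler method).
#' @return A `gf_reduced_trajectory` tibble: `time`, `block`, `task`, `loss`
#'   (`0.5 * sum(eps^2)`), gates `gate_*`, reduced weights `w_p<q>_t<m>`
#'   (mode-averaged), and coordinates `w_bar1`, `w_bar2`, `w_bar`, `c_bar`.
#' @export
simulate_reduced <- function(w0, c0, targets, block_length, tau_w = 1,
                             tau_c = 1, lambda_norm = 0, lambda_nonneg = 0,
                             norm_order = 1, dt = tau_c / 50,
                             method = c("lsoda", "euler"),
                             constrain_sum = FALSE, record_every = 1L,
                             rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  if (is.matrix(w0)) w0 <- array(w0, dim = c(dim(w0), 1L))
  p <- dim(w0)[1]
  a_modes <- dim(w0)[3]
  stopifnot(dim(w0)[2] == 2L, length(c0) == p, all(targets %in% 1:2),
            block_length > 0)

  nw <- length(w0)
  deriv <- function(state, target) {
    w <- array(state[seq_len(nw)], dim = dim(w0))
    cc <- state[nw + seq_len(p)]
    eps <- reduced_eps(w, cc, target)
    dw <- array(0, dim(w0))
    for (m in 1:2) dw[, m, ] <- outer(cc, eps[m, ]) / tau_w
    task <- vapply(seq_len(p), function(q) sum(w[q, , ] * eps), numeric(1))
    dc <- if (constrain_sum) {
      dc0 <- task / tau_c
      dc0 - mean(dc0)
    } else {
      (task - gate_reg_grad_r(cc, lambda_norm, lambda_nonneg, norm_order)) / tau_c
    }
    list(d = c(as.vector(dw), dc), eps = eps)
  }

  state <- c(as.vector(w0), c0)
  rows <- vector("list", length(targets))
  for (b in seq_along(targets)) {
    target <- targets[b]
    t0 <- (b - 1) * block_length
    if (method == "euler") {
      n_steps <- max(1L, as.integer(round(block_length / dt)))
      dt_eff <- block_length / n_steps
      keep <- seq(0L, n_steps - 1L, by = record_every)
      out <- matrix(NA_real_, length(keep), 1 + length(state))
      r <- 1L
      for (s in seq_len(n_steps) - 1L) {
        if (s %% record_every == 0L) {
          out[r, ] <- c(t0 + s * dt_eff, state)
          r <- r + 1L
        }
        state <- state + dt_eff * deriv(state, target)$d
      }
    } else {
      times <- seq(0, block_length, by = dt * record_every)
      sol <- deSolve::ode(
        y = state, times = times, parms = NULL,
        func = function(t, y, parms) list(deriv(y, target)$d),
        method = "lsoda", rtol = rtol, atol = atol)
      out <- cbind(t0 + sol[, 1], sol[, -1, drop = FALSE])
      out <- out[-nrow(out), , drop = FALSE]  # half-open block
      state <- sol[nrow(sol), -1]
    }
    rows[[b]] <- cbind(out, block = b, task = target)
  }
  res <- do.call(rbind, rows)

  times <- res[, 1]
  states <- res[, 1 + seq_len(length(state)), drop = FALSE]
  blocks <- as.integer(res[, ncol(res) - 1L])
  tasks <- as.integer(res[, ncol(res)])

  to_row <- function(i) {
    w <- array(states[i, seq_len(nw)], dim = dim(w0))
    cc <- states[i, nw + seq_len(p)]
    eps <- reduced_eps(w, cc, tasks[i])
    wbar <- reduced_coords(w, cc)
    wm <- apply(w, c(1, 2), mean)
    c(loss = 0.5 * sum(eps^2), stats::setNames(cc, paste0("gate_", seq_len(p))),
      stats::setNames(as.vector(t(wm)),
                      paste0("w_p", rep(seq_len(p), each = 2), "_t", rep(1:2, p))),
      unlist(wbar))
  }
  first <- to_row(1L)
  obs <- t(vapply(seq_along(times), to_row, first))
  colnames(obs) <- names(first)
  tbl <- dplyr::bind_cols(
    tibble::tibble(time = times, block = blocks, task = tasks),
    tibble::as_tibble(obs))
  structure(tbl,
            class = c("gf_reduced_trajectory", class(tibble::tibble())),
            pars = list(tau_w = tau_w, tau_c = tau_c,
                        lambda_norm = lambda_norm,
                        lambda_nonneg = lambda_nonneg,
                        norm_order = norm_order,
                        constrain_sum = constrain_sum, dt = dt,
                        block_length = block_length, method = method),
            final_state = list(w = array(state[seq_len(nw)], dim = dim(w0)),
                               c = state[nw + seq_len(p)]))
}

#' Adaptation of a fully specialized state over one block
#'
#' Starts from the fully specialized, fully separated reduced state
#' (`w[p, m] = 1{p == m}`, gates `(1, 0)`) and integrates one block of
#' adaptation to teacher 2 in the strong-L1 setting (large `lambda_norm`
#' keeps `sum_p c_p` within about `1/lambda_norm` of 1). The resulting
#' `(c_bar, w_bar)` path is the one described by
#' [exact_symmetric_solution()]: the gates traverse from `c_bar = 1` to
#' `c_bar = -1` while specialization dips by at most `tau_c / (2 tau_w)` and
#' recovers.
#'
#' @param tau_c Gate time constant.
#' @param tau_w Weight time constant (default 1).
#' @param lambda_norm,lambda_nonneg Regularization weights (defaults 1000,
#'   the strong-regularization setting).
#' @param block_length Duration of the adaptation block (default 25 time
#'   units, enough for complete adaptation up to `tau_c = tau_w = 1`).
#' @param dt Output resolution (default `block_length / 2000`; the adaptive
#'   integrator's accuracy does not depend on it).
#' @param method Integrator, as in [simulate_reduced()].
#' @param constrain_sum Use the exact simplex constraint instead of strong
#'   regularization.
#' @return A `gf_reduced_trajectory`.
#' @export
block_adaptation <- function(tau_c, tau_w = 1, lambda_norm = 1000,
                             lambda_nonneg = 1000, block_length = 25,
                             dt = block_length / 2000, method = "lsoda",
                             constrain_sum = FALSE) {
  simulate_reduced(w0 = diag(2), c0 = c(1, 0), targets = 2L,
                   block_length = block_length, tau_w = tau_w, tau_c = tau_c,
                   lambda_norm = lambda_norm, lambda_nonneg = lambda_nonneg,
                   norm_order = 1, dt = dt, method = method,
                   constrain_sum = constrain_sum)
}
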