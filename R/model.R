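# The gated linear student: forward map, losses, exact gradients.

#' Construct a gated linear network
#'
#' The student is a sum of `p` linear pathways, each a `d_out` by `d_in`
#' weight matrix `W_p` multiplied by a gating variable `c_p`:
#' `y = sum_p c_p W_p x` (with `gate_mode = "per_row"`, each output row `i`
#' carries its own gate `c_{p,i}`). Weights and gates are trained jointly by
#' gradient flow on `L_task + lambda_norm * L_norm + lambda_nonneg * L_nonneg`,
#' but on different timescales: `tau_w` for the weights and (typically much
#' faster) `tau_c` for the gates. The gate regularizers bound total gate
#' activity around 1 (`L_norm = (||c||_k - 1)^2 / 2`, `k = norm_order`) and
#' penalize negative gates (`L_nonneg = sum_p max(0, -c_p)`), making the gates
#' behave like bounded, nonnegative neural activations.
#'
#' Weights are initialized i.i.d. Gaussian with standard deviation
#' `sigma0 / sqrt(d_in)` (small, so pathways start unspecialized); all gates
#' start at 1/2.
#'
#' @param p Number of pathways (students).
#' @param d_in,d_out Input/output dimensions (must match the teachers).
#' @param tau_w,tau_c Time constants of the weight and gate gradient flow.
#' @param lambda_norm,lambda_nonneg Regularization weights on the gate norm
#'   and nonnegativity penalties.
#' @param norm_order Norm used by the bounding penalty: 1 (default) or 2.
#' @param gate_mode `"scalar"` (one gate per pathway) or `"per_row"` (one gate
#'   per pathway and output row; regularizers then act independently on each
#'   row's gate vector across pathways).
#' @param sigma0 Initialization scale of the weights.
#' @param seed Optional seed for the weight initialization.
#' @return An object of class `gf_network` with elements `weights` (list of
#'   `p` matrices), `gates` (length-`p` vector, or `p` x `d_out` matrix in
#'   per-row mode) and the hyperparameters.
#' @examples
#' net <- gated_network(p = 2, d_in = 16, d_out = 4, seed = 1)
#' x <- rnorm(16)
#' predict(net, x)
#' @export
gated_network <- function(p = 2, d_in = 32, d_out = 8, tau_w = 1.3,
                          tau_c = 0.03, lambda_norm = 1, lambda_nonneg = 1,
                          norm_order = 1, gate_mode = c("scalar", "per_row"),
                          sigma0 = 0.01, seed = NULL) {
  gate_mode <- match.arg(gate_mode)
  stopifnot(p >= 1, d_in >= 1, d_out >= 1, tau_w > 0, tau_c > 0,
            lambda_norm >= 0, lambda_nonneg >= 0, norm_order %in% c(1, 2),
            sigma0 >= 0)
  draw <- function() {
    lapply(seq_len(p), function(q)
      matrix(rnorm(d_out * d_in, sd = sigma0 / sqrt(d_in)), d_out, d_in))
  }
  weights <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  gates <- if (gate_mode == "scalar") rep(0.5, p) else matrix(0.5, p, d_out)
  structure(
    list(weights = weights, gates = gates, p = as.integer(p),
         d_in = as.integer(d_in), d_out = as.integer(d_out),
         tau_w = tau_w, tau_c = tau_c, lambda_norm = lambda_norm,
         lambda_nonneg = lambda_nonneg, norm_order = as.integer(norm_order),
         gate_mode = gate_mode, sigma0 = sigma0, seed = seed),
    class = "gf_network")
}

#' @export
print.gf_network <- function(x, ...) {
  cat(sprintf(
    "<gf_network> %d path(s), %d x %d, tau_w %g, tau_c %g, lambda (%g, %g), L%d gates (%s)\n",
    x$p, x$d_out, x$d_in, x$tau_w, x$tau_c, x$lambda_norm, x$lambda_nonneg,
    x$norm_order, x$gate_mode))
  invisible(x)
}

gate_matrix <- function(net) {
  if (net$gate_mode == "scalar") matrix(net$gates, ncol = 1) else net$gates
}

#' Forward pass of a gated network
#'
#' @param object A [gated_network()].
#' @param x Input: a length-`d_in` vector or `d_in` x `n` matrix.
#' @param ... Unused.
#' @return Output vector (or `d_out` x `n` matrix).
#' @export
predict.gf_network <- function(object, x, ...) {
  x <- as.matrix(x)
  if (nrow(x) != object$d_in) {
    abort(sprintf("input has %d rows; expected d_in = %d", nrow(x), object$d_in),
          class = "gf_dim_error")
  }
  y <- matrix(0, object$d_out, ncol(x))
  cm <- gate_matrix(object)
  for (q in seq_len(object$p)) {
    wx <- object$weights[[q]] %*% x
    y <- y + if (object$gate_mode == "scalar") cm[q, 1] * wx else cm[q, ] * wx
  }
  if (ncol(y) == 1L) drop(y) else y
}

#' Empirical task loss on a batch
#'
#' Mean over samples of `0.5 * sum_i (y_star_i - y_i)^2`.
#'
#' @param net A [gated_network()].
#' @param batch A list with matrices `x` (`d_in` x `n`) and `y` (`d_out` x
#'   `n`), e.g. from [sample_batch()].
#' @return Nonnegative scalar.
#' @export
task_loss <- function(net, batch) {
  stopifnot(inherits(net, "gf_network"), is.list(batch), ncol(batch$x) >= 1)
  err <- batch$y - as.matrix(predict(net, batch$x))
  0.5 * sum(err^2) / ncol(batch$x)
}

#' Exact expected task loss under standard-Gaussian inputs
#'
#' For unit-covariance inputs the expectation of the batch loss has the closed
#' form `0.5 * ||W_star - sum_q c_q W_q||_F^2` (per-row gates: rows weighted by
#' their own gates). This is the deterministic loss that the expectation-mode
#' dynamics descend.
#'
#' @param net A [gated_network()].
#' @param teacher The active teacher matrix.
#' @return Nonnegative scalar.
#' @export
expected_task_loss <- function(net, teacher) {
  0.5 * sum(error_matrix(net, teacher)^2)
}

error_matrix <- function(net, teacher) {
  stopifnot(inherits(net, "gf_network"), is.matrix(teacher))
  e <- teacher
  cm <- gate_matrix(net)
  for (q in seq_len(net$p)) {
    e <- e - if (net$gate_mode == "scalar") cm[q, 1] * net$weights[[q]] else
      cm[q, ] * net$weights[[q]]
  }
  e
}

#' Gate regularization losses
#'
#' Returns the two components of the gate penalty: the bounding term
#' `0.5 * (||c||_k - 1)^2` and the nonnegativity hinge `sum_p max(0, -c_p)`
#' (unweighted; the `lambda` factors apply them in the total loss). In per-row
#' mode each output row's gate vector is penalized independently and the
#' components are summed over rows.
#'
#' @param net A [gated_network()].
#' @return Named list with `norm` and `nonneg`.
#' @export
reg_loss <- function(net) {
  cm <- gate_matrix(net)
  k <- net$norm_order
  norm_of <- function(v) if (k == 1) sum(abs(v)) else sqrt(sum(v^2))
  norm_term <- sum(apply(cm, 2, function(v) 0.5 * (norm_of(v) - 1)^2))
  nonneg_term <- sum(pmax(0, -cm))
  list(norm = norm_term, nonneg = nonneg_term)
}

gate_reg_grad_r <- function(v, lambda_norm, lambda_nonneg, k) {
  g <- numeric(length(v))
  if (lambda_norm > 0) {
    if (k == 1) {
      g <- g + lambda_norm * (sum(abs(v)) - 1) * sign(v)
    } else {
      nv <- sqrt(sum(v^2))
      if (nv > 0) g <- g + lambda_norm * (nv - 1) * v / nv
    }
  }
  if (lambda_nonneg > 0) g <- g - lambda_nonneg * (v < 0)
  g
}

#' Loss gradients of the gated network
#'
#' Gradients of the total loss `L_task + lambda_norm L_norm +
#' lambda_nonneg L_nonneg` with respect to weights and gates. In
#' `"expectation"` mode the exact input-averaged gradients are used: with
#' error matrix `E = W_star - sum_q c_q W_q`, the task parts are
#' `dL/dW_p = -c_p E` and `dL/dc_p = -<W_p, E>` (Frobenius inner product);
#' per-row gates apply the same expressions row by row. In `"minibatch"` mode
#' the empirical gradients of the sampled batch loss are returned.
#'
#' @param net A [gated_network()].
#' @param teacher Active teacher matrix.
#' @param mode `"expectation"` or `"minibatch"`.
#' @param batch Required in minibatch mode: a list with `x` and `y`.
#' @return A list with `dW` (list of matrices), `dc` (gate-shaped), and
#'   `components` holding the task/norm/nonneg parts of the gate gradient.
#' @export
loss_gradients <- function(net, teacher, mode = c("expectation", "minibatch"),
                           batch = NULL) {
  mode <- match.arg(mode)
  cm <- gate_matrix(net)
  per_row <- net$gate_mode == "per_row"

  if (mode == "expectation") {
    e <- error_matrix(net, teacher)
    dW <- lapply(seq_len(net$p), function(q) {
      if (!per_row) -cm[q, 1] * e else -cm[q, ] * e
    })
    dc_task <- if (!per_row) {
      vapply(seq_len(net$p), function(q) -sum(net$weights[[q]] * e), numeric(1))
    } else {
      t(vapply(seq_len(net$p),
               function(q) -rowSums(net$weights[[q]] * e), numeric(net$d_out)))
    }
  } else {
    if (is.null(batch)) {
      abort("minibatch mode requires a `batch`", class = "gf_invalid_config")
    }
    n <- ncol(batch$x)
    err <- batch$y - as.matrix(predict(net, batch$x))  # d_out x n
    dW <- vector("list", net$p)
    dc_task <- if (!per_row) numeric(net$p) else matrix(0, net$p, net$d_out)
    for (q in seq_len(net$p)) {
      wx <- net$weights[[q]] %*% batch$x
      if (!per_row) {
        dW[[q]] <- -(cm[q, 1] / n) * err %*% t(batch$x)
        dc_task[q] <- -sum(wx * err) / n
      } else {
        dW[[q]] <- -(cm[q, ] / n) * (err %*% t(batch$x))
        dc_task[q, ] <- -rowSums(wx * err) / n
      }
    }
  }

  reg <- if (!per_row) {
    matrix(gate_reg_grad_r(cm[, 1], net$lambda_norm, net$lambda_nonneg,
                           net$norm_order), ncol = 1)
  } else {
    apply(cm, 2, function(v)
      gate_reg_grad_r(v, net$lambda_norm, net$lambda_nonneg, net$norm_order))
  }
  dc_task_m <- if (!per_row) matrix(dc_task, ncol = 1) else dc_task
  dc <- dc_task_m + reg
  if (!per_row) dc <- drop(dc)

  list(dW = dW, dc = dc,
       components = list(task = if (!per_row) drop(dc_task_m) else dc_task_m,
                         reg = if (!per_row) drop(reg) else reg))
}

#' Forgetful control model
#'
#' Returns a copy of the network with the gate constraints removed: the gate
#' timescale is set equal to the weight timescale and both regularization
#' weights to zero. Weights and gates are untouched. This is the matched
#' control that stays in the forgetful learning regime.
#'
#' @param net A [gated_network()].
#' @return A `gf_network`.
#' @export
forgetful_baseline <- function(net) {
  stopifnot(inherits(net, "gf_network"))
  net$tau_c <- net$tau_w
  net$lambda_norm <- 0
  net$lambda_nonneg <- 0
  net
}
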