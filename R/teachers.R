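# Teacher ensembles and the blocked task curriculum.

#' Generate a set of linear teachers
#'
#' Each of the `m` tasks is defined by a ground-truth linear map (a *teacher*),
#' a `d_out` by `d_in` matrix applied to standard-Gaussian inputs. By default
#' the stacked rows of all teachers are mutually orthogonal, so the tasks make
#' orthogonal demands on the same input, and every row is scaled to
#' `row_norm`. With `orthogonal = FALSE` and `correlation = rho > 0`,
#' corresponding rows of different teachers share a common component so that
#' their pairwise cosine is `rho` (a hook for studying related tasks).
#'
#' @param m Number of tasks/teachers.
#' @param d_in,d_out Input and output dimension of every teacher.
#' @param row_norm Euclidean norm given to each teacher row (default 1, so
#'   every teacher has unit singular values).
#' @param orthogonal If `TRUE` (default), orthogonalize the `m * d_out`
#'   stacked rows; requires `m * d_out <= d_in`.
#' @param correlation Pairwise cosine between corresponding rows of different
#'   teachers; only meaningful with `orthogonal = FALSE`.
#' @param seed Optional integer seed; the construction is deterministic given
#'   the seed and leaves the global RNG state untouched.
#'
#' @return An object of class `gf_teachers`: a list with elements `weights`
#'   (list of `m` matrices), `svd` (per-teacher singular triplets), `m`,
#'   `d_in`, `d_out`, `row_norm`, `orthogonal`.
#'
#' @examples
#' tc <- make_teachers(m = 2, d_in = 16, d_out = 4, seed = 1)
#' crossprod(t(rbind(tc$weights[[1]], tc$weights[[2]])))  # ~ identity
#' @export
make_teachers <- function(m = 2, d_in = 32, d_out = 8, row_norm = 1,
                          orthogonal = TRUE, correlation = 0, seed = NULL) {
  stopifnot(m >= 1, d_in >= 1, d_out >= 1, row_norm > 0)
  if (orthogonal && correlation != 0) {
    abort("`correlation` must be 0 when `orthogonal = TRUE`.",
          class = "gf_invalid_config")
  }
  if (correlation < 0 || correlation >= 1) {
    abort("`correlation` must lie in [0, 1).", class = "gf_invalid_config")
  }
  if (orthogonal && m * d_out > d_in) {
    abort(sprintf(
      "cannot build %d orthogonal rows in %d input dimensions (m * d_out <= d_in required)",
      m * d_out, d_in), class = "gf_invalid_config")
  }
  if (!orthogonal && correlation > 0 && (m + 1) * d_out > d_in) {
    abort("correlated construction requires (m + 1) * d_out <= d_in",
          class = "gf_invalid_config")
  }

  draw <- function() {
    if (orthogonal) {
      g <- matrix(rnorm(m * d_out * d_in), nrow = m * d_out, ncol = d_in)
      # orthonormalize the stacked rows, then scale each to row_norm
      q <- t(qr.Q(qr(t(g)))[, seq_len(m * d_out), drop = FALSE])
      rows <- q * row_norm
    } else if (correlation > 0) {
      # shared component a_j per row index, plus teacher-specific orthogonal parts
      g <- matrix(rnorm((m + 1) * d_out * d_in), nrow = (m + 1) * d_out, ncol = d_in)
      q <- t(qr.Q(qr(t(g)))[, seq_len((m + 1) * d_out), drop = FALSE])
      shared <- q[seq_len(d_out), , drop = FALSE]
      rows <- matrix(0, m * d_out, d_in)
      for (k in seq_len(m)) {
        own <- q[k * d_out + seq_len(d_out), , drop = FALSE]
        rows[(k - 1L) * d_out + seq_len(d_out), ] <-
          (sqrt(correlation) * shared + sqrt(1 - correlation) * own) * row_norm
      }
      rows
    } else {
      rows <- matrix(rnorm(m * d_out * d_in), nrow = m * d_out, ncol = d_in)
      rows <- rows / sqrt(rowSums(rows^2)) * row_norm
    }
    rows
  }
  rows <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  weights <- lapply(seq_len(m), function(k) {
    w <- rows[(k - 1L) * d_out + seq_len(d_out), , drop = FALSE]
    dimnames(w) <- NULL
    w
  })
  structure(
    list(weights = weights,
         svd = lapply(weights, function(w) svd(w)),
         m = as.integer(m), d_in = as.integer(d_in), d_out = as.integer(d_out),
         row_norm = row_norm, orthogonal = orthogonal,
         correlation = correlation, seed = seed),
    class = "gf_teachers")
}

#' @export
print.gf_teachers <- function(x, ...) {
  cat(sprintf("<gf_teachers> %d teacher(s), %d x %d, %s, row norm %g\n",
              x$m, x$d_out, x$d_in,
              if (x$orthogonal) "mutually orthogonal rows" else
                sprintf("row correlation %g", x$correlation),
              x$row_norm))
  invisible(x)
}

#' Compose teachers into new tasks
#'
#' Builds the composed tasks used in the generalization experiments: either the
#' additive composition of pairs of teachers (`type = "sum"`) or row-wise
#' compositions that take alternating rows from the two teachers of each pair
#' (`type = "rows"`: odd rows from the first, even rows from the second).
#'
#' @param teachers A [make_teachers()] set.
#' @param pairs List of integer pairs (teacher indices) to compose; defaults to
#'   all pairs in lexicographic order, e.g. (1,2), (1,3), (2,3) for `m = 3`.
#' @param type `"sum"` or `"rows"`.
#' @return A `gf_teachers` object holding the composed maps (not orthogonal).
#' @export
compose_teachers <- function(teachers, pairs = NULL, type = c("sum", "rows")) {
  stopifnot(inherits(teachers, "gf_teachers"))
  type <- match.arg(type)
  pairs <- pairs %||% utils::combn(teachers$m, 2, simplify = FALSE)
  weights <- lapply(pairs, function(pr) {
    a <- teachers$weights[[pr[[1]]]]
    b <- teachers$weights[[pr[[2]]]]
    if (type == "sum") {
      a + b
    } else {
      w <- a
      even <- seq(2, nrow(a), by = 2)
      w[even, ] <- b[even, , drop = FALSE]
      w
    }
  })
  out <- teachers
  out$weights <- weights
  out$svd <- lapply(weights, svd)
  out$m <- length(weights)
  out$orthogonal <- FALSE
  out$composed_from <- pairs
  out$composed_type <- type
  out
}

#' Define a blocked task curriculum
#'
#' Tasks are presented in contiguous blocks of duration `block_length` (in
#' simulation time units), switching sequentially through `task_order`
#' (cyclically repeated). Block boundaries follow the half-open convention: the
#' b-th block covers times `[(b-1) * block_length, b * block_length)`.
#'
#' @param n_blocks Number of blocks.
#' @param block_length Duration of each block, in time units.
#' @param n_tasks Number of distinct tasks; used to build the default cyclic
#'   `task_order` 1, 2, ..., `n_tasks`, 1, ...
#' @param task_order Optional explicit order (1-based task indices); recycled
#'   cyclically over blocks.
#' @param sampling `"expectation"` for deterministic gradients under the exact
#'   input average, or `"minibatch"` for stochastic gradients over sampled
#'   Gaussian batches.
#' @param batch_size Batch size per integration step in minibatch mode.
#' @param seed Seed for data sampling in minibatch mode (independent of the
#'   network-initialization seed).
#' @return An object of class `gf_curriculum`.
#' @examples
#' cur <- make_curriculum(n_blocks = 6, block_length = 1, n_tasks = 2)
#' active_task(c(0, 0.5, 1, 2.5), cur)
#' @export
make_curriculum <- function(n_blocks, block_length = 1, n_tasks = 2,
                            task_order = NULL,
                            sampling = c("expectation", "minibatch"),
                            batch_size = 32L, seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(n_blocks >= 0, block_length > 0, batch_size >= 1)
  task_order <- task_order %||% seq_len(n_tasks)
  task_order <- as.integer(task_order)
  if (any(task_order < 1) || any(task_order > n_tasks)) {
    abort("`task_order` entries must be task indices in 1..n_tasks.",
          class = "gf_invalid_config")
  }
  structure(
    list(n_blocks = as.integer(n_blocks), block_length = block_length,
         n_tasks = as.integer(n_tasks), task_order = task_order,
         sampling = sampling, batch_size = as.integer(batch_size), seed = seed,
         total_time = n_blocks * block_length),
    class = "gf_curriculum")
}

#' @export
print.gf_curriculum <- function(x, ...) {
  cat(sprintf(
    "<gf_curriculum> %d block(s) of length %g (total time %g), order [%s] cyclic, %s mode\n",
    x$n_blocks, x$block_length, x$total_time,
    paste(x$task_order, collapse = ", "), x$sampling))
  invisible(x)
}

#' Active task at given times
#'
#' Returns the 1-based task index scheduled at each time in `t`, using the
#' half-open block convention: block `b` (1-based) is active on
#' `[(b-1) * block_length, b * block_length)`.
#'
#' @param t Numeric vector of times, all `>= 0`.
#' @param curriculum A [make_curriculum()] object.
#' @return Integer vector of task indices.
#' @export
active_task <- function(t, curriculum) {
  stopifnot(inherits(curriculum, "gf_curriculum"))
  if (any(t < 0)) abort("times must be nonnegative", class = "gf_domain_error")
  block <- floor(t / curriculum$block_length)
  ord <- curriculum$task_order
  ord[(block %% length(ord)) + 1L]
}

#' Sample Gaussian input/label batches from a teacher
#'
#' Inputs are i.i.d. standard normal per coordinate; labels are the exact
#' teacher responses `y = W x`.
#'
#' @param teacher A teacher matrix (`d_out` x `d_in`).
#' @param n Number of samples.
#' @param seed Optional seed; the draw is bit-reproducible given `(seed, n)`.
#' @return A list with `x` (`d_in` x `n`) and `y` (`d_out` x `n`).
#' @export
sample_batch <- function(teacher, n, seed = NULL) {
  stopifnot(is.matrix(teacher), n >= 1)
  draw <- function() matrix(rnorm(ncol(teacher) * n), nrow = ncol(teacher))
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(x = x, y = teacher %*% x)
}
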