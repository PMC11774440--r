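# Observables: alignment, specialization, time-to-criterion, regime
# classification, switch-speed trends.

#' Row-averaged cosine alignment between a student and a teacher
#'
#' Mean over output rows of the cosine similarity between corresponding rows
#' of the two matrices. A zero row (e.g. at small initialization) contributes
#' 0 and triggers a warning.
#'
#' @param w Student matrix.
#' @param w_star Teacher matrix of the same shape.
#' @return A scalar in `[-1, 1]`.
#' @export
alignment <- function(w, w_star) {
  stopifnot(is.matrix(w), is.matrix(w_star), all(dim(w) == dim(w_star)))
  nw <- sqrt(rowSums(w^2))
  nt <- sqrt(rowSums(w_star^2))
  ok <- nw > 0 & nt > 0
  if (any(!ok)) {
    warn("zero row(s) encountered in alignment; contributing 0")
  }
  cosine <- numeric(nrow(w))
  cosine[ok] <- rowSums(w * w_star)[ok] / (nw[ok] * nt[ok])
  mean(cosine)
}

#' Total alignment between student and teacher ensembles
#'
#' Cosine similarity between the concatenated (row-stacked) student matrices
#' and the concatenated teachers, maximized over assignments of paths to
#' teachers (all permutations when the counts match; injective maps of the
#' smaller set otherwise). This is the single overall specialization measure
#' used in the phase diagrams: it approaches 1 only when each teacher is
#' matched by a distinct, positively aligned student.
#'
#' @param students A `gf_network`, or a list of student matrices.
#' @param teachers A [make_teachers()] set.
#' @return A scalar in `[-1, 1]`.
#' @export
total_alignment <- function(students, teachers) {
  stopifnot(inherits(teachers, "gf_teachers"))
  ws <- if (inherits(students, "gf_network")) students$weights else students
  if (length(ws) == 0L || teachers$m == 0L) {
    abort("empty student or teacher set", class = "gf_domain_error")
  }
  p <- length(ws)
  m <- teachers$m
  nw <- sqrt(sum(vapply(ws, function(w) sum(w^2), numeric(1))))
  nt <- sqrt(sum(vapply(teachers$weights, function(w) sum(w^2), numeric(1))))
  if (nw == 0 || nt == 0) return(0)
  ip <- outer(seq_len(p), seq_len(m),
              Vectorize(function(q, k) sum(ws[[q]] * teachers$weights[[k]])))
  ip <- matrix(ip, p, m)
  small <- min(p, m)
  large <- max(p, m)
  perms <- all_permutations(large)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    idx <- perms[i, seq_len(small)]
    num <- if (p <= m) sum(ip[cbind(seq_len(small), idx)]) else
      sum(ip[cbind(idx, seq_len(small))])
    best <- max(best, num)
  }
  best / (nw * nt)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub), n - 1L))
  }))
}

#' Per-block time to reach a loss criterion
#'
#' For each block, the elapsed time from block start until the recorded
#' (expected) task loss first drops below `threshold`; blocks that never reach
#' the criterion get the block length as a sentinel.
#'
#' @param traj A `gf_trajectory`.
#' @param threshold Positive loss criterion (default 0.1).
#' @return A tibble with columns `block` and `t_crit`.
#' @export
time_to_criterion <- function(traj, threshold = 0.1) {
  stopifnot(threshold > 0)
  bl <- attr(traj, "curriculum")$block_length
  tibble::as_tibble(traj) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      t_crit = {
        hit <- which(.data$loss < threshold)
        if (length(hit) == 0L) bl else
          .data$time[hit[1]] - (.data$block[1] - 1) * bl
      },
      .groups = "drop")
}

#' Classify a run as flexible or forgetful
#'
#' Operationalization of the two learning regimes: a run is *flexible* when
#' (i) its final total alignment exceeds `align_threshold` (weights ended up
#' specialized, one student per teacher) and (ii) adaptation accelerated with
#' practice, i.e. the mean time-to-criterion over the last quarter of blocks
#' is lower than over the first quarter. Otherwise it is *forgetful*.
#'
#' @param traj A `gf_trajectory` from a run with at least 8 blocks.
#' @param teachers Optional teacher set; defaults to the one recorded in the
#'   trajectory (used only if total alignment was not recorded).
#' @param align_threshold Alignment threshold (default 0.9).
#' @param threshold Loss criterion for the timing comparison (default 0.1).
#' @return `"flexible"` or `"forgetful"`.
#' @export
classify_regime <- function(traj, teachers = NULL, align_threshold = 0.9,
                            threshold = 0.1) {
  nb <- attr(traj, "curriculum")$n_blocks
  if (is.null(nb) || nb < 8L) {
    abort("regime classification needs a run of at least 8 blocks",
          class = "gf_insufficient_data")
  }
  final_align <- if ("total_alignment" %in% names(traj)) {
    traj$total_alignment[nrow(traj)]
  } else {
    net <- final_network(traj)
    total_alignment(net, teachers %||% attr(traj, "teachers"))
  }
  tc <- time_to_criterion(traj, threshold)
  q <- max(1L, nb %/% 4L)
  early <- mean(tc$t_crit[tc$block <= q])
  late <- mean(tc$t_crit[tc$block > nb - q])
  if (final_align > align_threshold && late < early) "flexible" else "forgetful"
}

#' Post-switch loss trend over blocks
#'
#' Mean loss over the initial fraction of each block (the post-switch window)
#' regressed against block index. A negative slope means switching gets faster
#' with practice; a nonnegative slope means it does not (or decelerates).
#'
#' @param traj A `gf_trajectory` with at least 4 blocks.
#' @param window Fraction of each block counted as the post-switch window
#'   (default 0.1).
#' @return A list with `slope`, `sign`, and the per-block tibble `per_block`
#'   (`block`, `post_switch_loss`).
#' @export
switch_speed_trend <- function(traj, window = 0.1) {
  nb <- attr(traj, "curriculum")$n_blocks
  if (is.null(nb) || nb < 4L) {
    abort("switch-speed trend needs at least 4 blocks",
          class = "gf_insufficient_data")
  }
  bl <- attr(traj, "curriculum")$block_length
  per_block <- tibble::as_tibble(traj) |>
    dplyr::group_by(.data$block) |>
    dplyr::filter(.data$time - (.data$block - 1) * bl <= window * bl + 1e-12) |>
    dplyr::summarise(post_switch_loss = mean(.data$loss), .groups = "drop")
  fit <- lsfit(per_block$block, per_block$post_switch_loss)
  slope <- unname(fit$coefficients[2])
  list(slope = slope, sign = sign(slope), per_block = per_block)
}
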