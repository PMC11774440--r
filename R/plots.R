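# ggplot2 figures for simulation results.

#' Plot a trajectory
#'
#' Faceted time courses of the loss, gates, and student-teacher alignments,
#' with block boundaries marked.
#'
#' @param object A `gf_trajectory`.
#' @param series Which series groups to show (any of `"loss"`, `"gates"`,
#'   `"alignment"`, `"norms"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gf_trajectory <- function(object,
                                   series = c("loss", "gates", "alignment"),
                                   ...) {
  long <- tidy(object) |>
    dplyr::mutate(group = dplyr::case_when(
      .data$series == "loss" ~ "loss",
      grepl("^gate_", .data$series) ~ "gates",
      grepl("^align_|^total_alignment$", .data$series) ~ "alignment",
      grepl("^wnorm_|_norm$", .data$series) ~ "norms",
      TRUE ~ NA_character_)) |>
    dplyr::filter(.data$group %in% series)
  bl <- attr(object, "curriculum")$block_length
  nb <- attr(object, "curriculum")$n_blocks
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_vline(xintercept = seq(0, nb) * bl, colour = "grey85",
                        linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase diagram
#'
#' Heatmap of the seed-averaged final total alignment over the grid.
#'
#' @param object A `gf_phase_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gf_phase_grid <- function(object, ...) {
  axis2 <- attr(object, "axis2")
  cells <- tidy(object)
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(signif(.data$block_length, 3)),
                                      y = factor(signif(.data[[axis2]], 3)),
                                      fill = .data$mean_alignment)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "grey20",
                                 high = "gold") +
    ggplot2::labs(x = "block length", y = axis2, fill = "total\nalignment") +
    ggplot2::theme_minimal()
}

#' Plot a reduced-dynamics trajectory in the specialization plane
#'
#' The `(c_bar, w_bar)` path of a reduced simulation, e.g. one block of
#' adaptation from the specialized state, optionally with the closed-form
#' symmetric solution overlaid.
#'
#' @param object A `gf_reduced_trajectory`.
#' @param closed_form Overlay [exact_symmetric_solution()] (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gf_reduced_trajectory <- function(object, closed_form = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$c_bar, y = .data$w_bar)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::labs(x = "gate separation (c bar)",
                  y = "weight specialization (w bar)") +
    ggplot2::theme_minimal()
  if (closed_form) {
    pars <- attr(object, "pars")
    cb <- seq(-1, 1, length.out = 201)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(
        c_bar = cb,
        w_bar = exact_symmetric_solution(cb, pars$tau_c, pars$tau_w)),
      linetype = "dashed", colour = "black")
  }
  p
}

#' Plot a regime comparison
#'
#' Mean time-to-criterion per block with standard-error ribbons, one line per
#' model.
#'
#' @param object A `gf_regime_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gf_regime_comparison <- function(object, ...) {
  s <- regime_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$block, y = .data$mean_t_crit,
                                  colour = .data$model, fill = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_t_crit - .data$se_t_crit,
      ymax = .data$mean_t_crit + .data$se_t_crit), alpha = 0.2,
      colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "block", y = "time to criterion") +
    ggplot2::theme_minimal()
}
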