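# broom-style tidiers for simulation results.

#' Tidy a trajectory into long format
#'
#' Pivots all recorded series (loss, gates, weight norms, alignments, update
#' norms) into a long tibble, convenient for faceted plotting and grouped
#' summaries.
#'
#' @param x A `gf_trajectory` (or `gf_deep_trajectory`).
#' @param ... Unused.
#' @return A tibble with columns `time`, `block`, `task`, `series`, `value`.
#' @export
tidy.gf_trajectory <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-dplyr::all_of(c("time", "block", "task")),
                        names_to = "series", values_to = "value")
}

#' @rdname tidy.gf_trajectory
#' @export
tidy.gf_deep_trajectory <- tidy.gf_trajectory

#' One-row summary of a trajectory
#'
#' @param x A `gf_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: `n_records`, `n_blocks`, `total_time`,
#'   `final_loss`, `min_loss`, `final_total_alignment` (NA if not recorded).
#' @export
glance.gf_trajectory <- function(x, ...) {
  cur <- attr(x, "curriculum")
  tibble::tibble(
    n_records = nrow(x),
    n_blocks = cur$n_blocks %||% NA_integer_,
    total_time = cur$total_time %||% NA_real_,
    final_loss = if (nrow(x)) x$loss[nrow(x)] else NA_real_,
    min_loss = if (nrow(x)) min(x$loss) else NA_real_,
    final_total_alignment = if ("total_alignment" %in% names(x) && nrow(x))
      x$total_alignment[nrow(x)] else NA_real_)
}

#' @rdname glance.gf_trajectory
#' @export
glance.gf_deep_trajectory <- function(x, ...) {
  cur <- attr(x, "curriculum")
  tibble::tibble(
    n_records = nrow(x),
    n_blocks = cur$n_blocks %||% NA_integer_,
    total_time = cur$total_time %||% NA_real_,
    final_loss = if (nrow(x)) x$loss[nrow(x)] else NA_real_,
    min_loss = if (nrow(x)) min(x$loss) else NA_real_,
    final_total_alignment = NA_real_)
}

#' Summaries of a phase diagram
#'
#' `tidy()` averages the per-seed alignments per cell; `glance()` reports
#' grid shape and failure count.
#'
#' @param x A `gf_phase_grid`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gf_phase_grid <- function(x, ...) {
  axis2 <- attr(x, "axis2")
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$block_length, .data[[axis2]]) |>
    dplyr::summarise(mean_alignment = mean(.data$total_alignment, na.rm = TRUE),
                     n_seeds = sum(!is.na(.data$total_alignment)),
                     .groups = "drop")
}

#' @rdname tidy.gf_phase_grid
#' @export
glance.gf_phase_grid <- function(x, ...) {
  axis2 <- attr(x, "axis2")
  tibble::tibble(
    n_cells = nrow(dplyr::distinct(tibble::as_tibble(x),
                                   .data$block_length, .data[[axis2]])),
    n_block_lengths = dplyr::n_distinct(x$block_length),
    n_axis2 = dplyr::n_distinct(x[[axis2]]),
    n_seeds = attr(x, "n_seeds"),
    total_time = attr(x, "total_time"),
    n_failed = sum(is.na(x$total_alignment)))
}
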