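# Trajectory serialization: tidy CSV plus a JSON metadata sidecar.

# hash of the column data only, independent of classes/attributes
trajectory_hash <- function(tbl) {
  cols <- lapply(tibble::as_tibble(tbl), function(col) as.vector(col))
  rlang::hash(stats::setNames(cols, names(tbl)))
}

#' Save / load a trajectory
#'
#' `save_trajectory()` writes the trajectory table to `<prefix>.csv` and a
#' JSON sidecar `<prefix>.json` holding the run metadata (hyperparameters,
#' curriculum, integration step, seed, package version) plus a hash of the
#' table, so a reload can detect corruption or mismatched files.
#' `load_trajectory()` reconstructs the classed trajectory and warns if the
#' stored hash does not match the data read back.
#'
#' @param traj A `gf_trajectory`.
#' @param prefix Path prefix (without extension).
#' @return `save_trajectory()` returns `prefix` invisibly;
#'   `load_trajectory()` returns a `gf_trajectory`.
#' @export
save_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "gf_trajectory"))
  net <- final_network(traj)
  cur <- attr(traj, "curriculum")
  meta <- list(
    package = "gateflow",
    version = as.character(packageVersion("gateflow")),
    dt = attr(traj, "dt"),
    record_every = attr(traj, "record_every"),
    model = if (!is.null(net)) {
      net[c("p", "d_in", "d_out", "tau_w", "tau_c", "lambda_norm",
            "lambda_nonneg", "norm_order", "gate_mode", "sigma0", "seed")]
    },
    curriculum = if (!is.null(cur)) {
      cur[c("n_blocks", "block_length", "n_tasks", "task_order", "sampling",
            "batch_size", "seed")]
    },
    data_hash = trajectory_hash(traj))
  meta$config_hash <- rlang::hash(meta[c("model", "curriculum", "dt")])
  # format doubles at 17 significant digits so the CSV round-trips bit-exactly
  out <- tibble::as_tibble(traj)
  out <- tibble::as_tibble(lapply(out, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }))
  readr::write_csv(out, paste0(prefix, ".csv"))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(prefix)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(json)) {
    abort(sprintf("missing trajectory files for prefix '%s'", prefix),
          class = "gf_io_error")
  }
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  # base read.csv: correctly-rounded double parsing (bit-exact round trip)
  tbl <- tibble::as_tibble(utils::read.csv(csv))
  tbl$block <- as.integer(tbl$block)
  tbl$task <- as.integer(tbl$task)
  if (!identical(trajectory_hash(tbl), meta$data_hash)) {
    warn("trajectory data hash does not match its metadata sidecar")
  }
  cur <- if (!is.null(meta$curriculum)) {
    make_curriculum(n_blocks = meta$curriculum$n_blocks,
                    block_length = meta$curriculum$block_length,
                    n_tasks = meta$curriculum$n_tasks,
                    task_order = meta$curriculum$task_order,
                    sampling = meta$curriculum$sampling,
                    batch_size = meta$curriculum$batch_size)
  }
  new_trajectory(tbl, NULL, cur, meta$dt, meta$record_every)
}
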