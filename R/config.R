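# YAML run configuration: schema validation and object construction.

config_schema <- function() {
  list(
    model = c("p", "d_in", "d_out", "tau_w", "tau_c", "lambda_norm",
              "lambda_nonneg", "norm_order", "gate_mode", "sigma0"),
    curriculum = c("m", "block_length", "n_blocks", "task_order", "sampling",
                   "batch_size"),
    integration = c("dt", "record_every"),
    seeds = c("init", "data", "teachers"),
    output_dir = NULL)
}

#' Assemble a run configuration
#'
#' A validated, nestable description of a full simulation: model
#' hyperparameters, curriculum, integration settings and seeds. All fields
#' have defaults matching the standard two-task configuration; unknown keys
#' are rejected.
#'
#' @param model,curriculum,integration,seeds Named lists overriding defaults
#'   (see the packaged `configs/fig2.yaml` for the full schema).
#' @param output_dir Optional output directory recorded in the config.
#' @return A list of class `gf_config`.
#' @export
gf_config <- function(model = list(), curriculum = list(),
                      integration = list(), seeds = list(),
                      output_dir = NULL) {
  cfg <- list(
    model = modifyList(
      list(p = 2L, d_in = 32L, d_out = 8L, tau_w = 1.3, tau_c = 0.03,
           lambda_norm = 1, lambda_nonneg = 1, norm_order = 1L,
           gate_mode = "scalar", sigma0 = 0.01), model),
    curriculum = modifyList(
      list(m = 2L, block_length = 1, n_blocks = 30L, task_order = NULL,
           sampling = "expectation", batch_size = 32L), curriculum),
    integration = modifyList(list(dt = NULL, record_every = NULL), integration),
    seeds = modifyList(list(init = 1L, data = 1L, teachers = 1L), seeds),
    output_dir = output_dir)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  schema <- config_schema()
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top) > 0) {
    abort(sprintf("unknown config section(s): %s",
                  paste(unknown_top, collapse = ", ")),
          class = "gf_invalid_config")
  }
  for (section in c("model", "curriculum", "integration", "seeds")) {
    unknown <- setdiff(names(cfg[[section]]), schema[[section]])
    if (length(unknown) > 0) {
      abort(sprintf("unknown key(s) in `%s`: %s", section,
                    paste(unknown, collapse = ", ")),
            class = "gf_invalid_config")
    }
  }
  m <- cfg$model
  check_pos <- function(value, key) {
    if (!is.numeric(value) || length(value) != 1 || value <= 0) {
      abort(sprintf("`%s` must be a positive number (got %s)", key,
                    paste(format(value), collapse = ", ")),
            class = "gf_invalid_config")
    }
  }
  check_pos(m$tau_w, "model.tau_w")
  check_pos(m$tau_c, "model.tau_c")
  check_pos(m$p, "model.p")
  check_pos(m$sigma0 + 1e-300, "model.sigma0")
  if (m$lambda_norm < 0 || m$lambda_nonneg < 0) {
    abort("model.lambda_norm and model.lambda_nonneg must be nonnegative",
          class = "gf_invalid_config")
  }
  if (!m$norm_order %in% c(1, 2)) {
    abort("model.norm_order must be 1 or 2", class = "gf_invalid_config")
  }
  if (!m$gate_mode %in% c("scalar", "per_row")) {
    abort("model.gate_mode must be 'scalar' or 'per_row'",
          class = "gf_invalid_config")
  }
  check_pos(cfg$curriculum$block_length, "curriculum.block_length")
  if (cfg$curriculum$n_blocks < 0) {
    abort("curriculum.n_blocks must be nonnegative", class = "gf_invalid_config")
  }
  if (!cfg$curriculum$sampling %in% c("expectation", "minibatch")) {
    abort("curriculum.sampling must be 'expectation' or 'minibatch'",
          class = "gf_invalid_config")
  }
  if (!is.null(cfg$integration$dt)) check_pos(cfg$integration$dt, "integration.dt")
  structure(cfg, class = "gf_config")
}

#' Read/write configurations as YAML
#'
#' `load_config()` parses and validates a YAML file against the schema
#' (unknown keys are rejected with the offending key named);
#' `save_config()` writes a configuration back out, so that
#' `load_config(save_config(cfg, path))` round-trips.
#'
#' @param path File path.
#' @return `load_config()`: a `gf_config`; `save_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "gf_io_error")
  }
  raw <- yaml::read_yaml(path)
  for (section in c("model", "curriculum", "integration", "seeds")) {
    raw[[section]] <- raw[[section]] %||% list()
  }
  defaults <- unclass(gf_config())
  cfg <- defaults
  for (section in c("model", "curriculum", "integration", "seeds")) {
    known <- names(raw[[section]]) %in% config_schema()[[section]]
    merged <- modifyList(defaults[[section]], raw[[section]][known])
    # keep unknown keys so validation can name them
    merged <- c(merged, raw[[section]][!known])
    # modifyList drops NULL-valued keys; keep optional keys present
    for (k in config_schema()[[section]]) {
      if (!k %in% names(merged)) merged[k] <- list(NULL)
    }
    cfg[[section]] <- merged[unique(c(names(defaults[[section]]),
                                      names(merged)))]
  }
  cfg$output_dir <- raw$output_dir
  extra <- setdiff(names(raw), names(config_schema()))
  for (k in extra) cfg[[k]] <- raw[[k]]
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A `gf_config`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gf_config"))
  yaml::write_yaml(purrr::map(unclass(cfg), function(x) x), path)
  invisible(path)
}

#' Instantiate objects from a configuration
#'
#' Helpers mapping a [gf_config()] onto the package's constructors, and
#' `run_from_config()` executing the whole configured simulation.
#'
#' @param cfg A `gf_config`.
#' @return The corresponding object ([gated_network()], [make_teachers()],
#'   [make_curriculum()]); `run_from_config()` returns the `gf_trajectory`.
#' @export
network_from_config <- function(cfg) {
  m <- cfg$model
  gated_network(p = m$p, d_in = m$d_in, d_out = m$d_out, tau_w = m$tau_w,
                tau_c = m$tau_c, lambda_norm = m$lambda_norm,
                lambda_nonneg = m$lambda_nonneg, norm_order = m$norm_order,
                gate_mode = m$gate_mode, sigma0 = m$sigma0,
                seed = cfg$seeds$init)
}

#' @rdname network_from_config
#' @export
teachers_from_config <- function(cfg) {
  make_teachers(m = cfg$curriculum$m, d_in = cfg$model$d_in,
                d_out = cfg$model$d_out, seed = cfg$seeds$teachers)
}

#' @rdname network_from_config
#' @export
curriculum_from_config <- function(cfg) {
  cc <- cfg$curriculum
  make_curriculum(n_blocks = cc$n_blocks, block_length = cc$block_length,
                  n_tasks = cc$m, task_order = cc$task_order,
                  sampling = cc$sampling, batch_size = cc$batch_size,
                  seed = cfg$seeds$data)
}

#' @rdname network_from_config
#' @export
run_from_config <- function(cfg) {
  net <- network_from_config(cfg)
  teachers <- teachers_from_config(cfg)
  cur <- curriculum_from_config(cfg)
  dt <- cfg$integration$dt %||% (net$tau_c / 50)
  simulate_dynamics(net, teachers, cur, dt = dt,
                    record_every = cfg$integration$record_every)
}
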