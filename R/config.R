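# YAML experiment configs with a strict schema: unknown keys are rejected and
# all defaults are materialized into the resolved config, which round-trips
# through dump_config()/load_config() unchanged.

CONFIG_SCHEMA <- list(
  experiment = EXPERIMENT_KINDS,
  variant = MODEL_VARIANTS,
  fixture = NULL, params = NULL, u1 = NULL, disturbance = NULL,
  t_span = NULL, d = NULL, horizon = NULL, epsilon = NULL,
  axis = NULL, values = NULL, doses = NULL, K_half = NULL, hill_n = NULL,
  basal = NULL, sensor_max = NULL, solver = NULL, out = NULL, seed = NULL)

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("config_error", "error")))
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    config_error("unknown key(s) in ", where, ": ",
                 paste(bad, collapse = ", "))
  }
}

#' Load and validate an experiment config
#'
#' Reads a YAML experiment description, validates it against a strict schema
#' (unknown keys anywhere are rejected; domain constraints such as
#' `0 <= d < 1` are enforced here), and materializes every default into the
#' returned object, so the resolved config is self-contained and
#' [dump_config()] of it reloads identically.
#'
#' A config names its `experiment` (one of `simulate`, `step`, `robustness`,
#' `sweep`, `qic-check`, `silencing`), a model `variant`, and a parameter
#' source: a `fixture` name (see [device_fixture_names()]) optionally
#' combined with `params` overrides, or a complete `params` block. Experiment
#' keys: `disturbance` (scalar `d` or `{breakpoints, values}`), `t_span`,
#' `d`, `horizon`, `epsilon`, `axis`/`values`, `doses`/`K_half`/`hill_n`/
#' `basal`, `solver` (`rtol`, `atol`, `n_grid`), `u1`, `out`, `seed`.
#'
#' @param path Path to a YAML file, or a list already parsed from one.
#' @return A fully resolved list of class `"experiment_config"`.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) config_error("config file not found: ", path)
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) config_error("config must be a YAML mapping")
  check_keys(cfg, names(CONFIG_SCHEMA), "config")
  if (is.null(cfg$experiment)) config_error("missing required key: experiment")
  if (!cfg$experiment %in% EXPERIMENT_KINDS) {
    config_error("experiment must be one of: ",
                 paste(EXPERIMENT_KINDS, collapse = ", "))
  }
  cfg$variant <- cfg$variant %||% "regulated"
  if (!cfg$variant %in% MODEL_VARIANTS) {
    config_error("variant must be one of: ",
                 paste(MODEL_VARIANTS, collapse = ", "))
  }
  if (!is.null(cfg$params)) check_keys(cfg$params, PARAM_KEYS, "params")
  if (is.null(cfg$fixture) && is.null(cfg$params)) {
    config_error("config needs a `fixture` name or a full `params` block")
  }
  # materialize the full parameter set
  p <- tryCatch(config_params(cfg), error = function(e) {
    config_error("invalid params: ", conditionMessage(e))
  })
  cfg$params <- unclass(p)[PARAM_KEYS[PARAM_KEYS != "actuator_saturation"]]
  if (!is.null(p$actuator_saturation)) {
    cfg$params$actuator_saturation <- p$actuator_saturation
  }
  cfg$u1 <- cfg$u1 %||% 1

  # disturbance block
  dist <- cfg$disturbance
  if (!is.null(dist)) {
    if (is.numeric(dist)) dist <- list(d = dist)
    check_keys(dist, c("d", "breakpoints", "values"), "disturbance")
    if (!is.null(dist$d)) {
      if (any(dist$d < 0) || any(dist$d >= 1)) {
        config_error("disturbance d violates 0 <= d < 1")
      }
      dist <- list(d = dist$d)
    } else {
      prof <- tryCatch(
        disturbance_profile(unlist(dist$breakpoints), unlist(dist$values)),
        error = function(e) config_error("invalid disturbance: ",
                                         conditionMessage(e)))
      dist <- list(breakpoints = prof$breakpoints, values = prof$values)
    }
  } else {
    dist <- list(d = 0)
  }
  cfg$disturbance <- dist

  if (!is.null(cfg$d) && (any(cfg$d < 0) || any(cfg$d >= 1))) {
    config_error("d violates 0 <= d < 1")
  }
  # per-experiment defaults
  cfg$d <- cfg$d %||% 0.5
  cfg$t_span <- as.numeric(unlist(cfg$t_span %||% c(0, 10)))
  cfg$horizon <- cfg$horizon %||% (8 / cfg$params$gamma)
  cfg$epsilon <- cfg$epsilon %||% 0.1
  cfg$axis <- cfg$axis %||% "disturbance"
  if (!cfg$axis %in% c("gain", "disturbance", "input")) {
    config_error("axis must be gain, disturbance or input")
  }
  cfg$values <- as.numeric(unlist(cfg$values %||%
    switch(cfg$axis, disturbance = seq(0, 0.9, by = 0.1),
           gain = 10^seq(-1, 1.5, length.out = 11),
           input = 10^seq(-2, 2, length.out = 11))))
  cfg$doses <- as.numeric(unlist(cfg$doses %||%
                                   c(0, 1, 3, 10, 30, 100, 300, 1000)))
  cfg$K_half <- cfg$K_half %||% 30
  cfg$hill_n <- cfg$hill_n %||% 1
  cfg$basal <- cfg$basal %||% 0
  cfg$sensor_max <- cfg$sensor_max %||% 100
  solver <- cfg$solver %||% list()
  check_keys(solver, c("rtol", "atol", "n_grid"), "solver")
  cfg$solver <- list(rtol = solver$rtol %||% 1e-8,
                     atol = solver$atol %||% 1e-10,
                     n_grid = as.integer(solver$n_grid %||% 500L))
  cfg <- cfg[intersect(names(CONFIG_SCHEMA), names(cfg))]
  structure(cfg, class = "experiment_config")
}

# Build device_params from a resolved or raw config.
config_params <- function(cfg) {
  base <- if (!is.null(cfg$fixture)) device_fixture(cfg$fixture) else NULL
  ov <- cfg$params %||% list()
  if (is.null(base)) {
    ov$D <- ov$D %||% 1
    do.call(device_params, ov)
  } else if (length(ov)) {
    do.call(update_params, c(list(base), ov))
  } else base
}

#' Serialize a resolved config back to YAML
#' @param config An [load_config()] result.
#' @param path Optional output file; if `NULL` the YAML text is returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
dump_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  txt <- yaml::as.yaml(unclass(config))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

config_disturbance <- function(cfg) {
  d <- cfg$disturbance
  if (!is.null(d$d)) constant_disturbance(d$d)
  else disturbance_profile(d$breakpoints, d$values)
}

#' Run the experiment described by a config
#'
#' Dispatches on `config$experiment`, runs the corresponding package
#' operation, writes the declared output files (tidy CSV for trajectories,
#' sweeps and dose responses; JSON for robustness and QIC reports) and echoes
#' the fully resolved config to stderr so every run is self-documenting.
#' Output files carry no timestamps: identical configs give byte-identical
#' files.
#'
#' @param config A path to a YAML config, or an [load_config()] result.
#' @param quiet Suppress the resolved-config echo.
#' @return The experiment's result object, invisibly.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  if (!inherits(config, "experiment_config")) config <- load_config(config)
  cfg <- config
  if (!quiet) {
    message("resolved config:\n", dump_config(cfg))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- config_params(cfg)
  sv <- cfg$solver
  res <- switch(cfg$experiment,
    "simulate" = simulate_device(p, variant = cfg$variant,
                                 disturbance = config_disturbance(cfg),
                                 u1 = cfg$u1, t_span = cfg$t_span,
                                 n_grid = sv$n_grid, rtol = sv$rtol,
                                 atol = sv$atol),
    "step" = step_response(p, variant = cfg$variant, d_step = cfg$d,
                           u1 = cfg$u1, horizon = cfg$horizon,
                           n_grid = sv$n_grid, rtol = sv$rtol,
                           atol = sv$atol),
    "robustness" = robustness(p, variant = cfg$variant, d_active = cfg$d,
                              u1 = cfg$u1),
    "sweep" = sweep_device(p, variant = cfg$variant, axis = cfg$axis,
                           values = cfg$values, d_active = cfg$d,
                           u1 = cfg$u1),
    "qic-check" = qic_check(p, epsilon = cfg$epsilon),
    "silencing" = silencing_dose_response(p, doses = cfg$doses,
                                          K_half = cfg$K_half,
                                          hill_n = cfg$hill_n,
                                          basal = cfg$basal,
                                          sensor_max = cfg$sensor_max,
                                          u1 = cfg$u1))
  if (!is.null(cfg$out)) write_result(res, cfg$out)
  invisible(res)
}

write_result <- function(res, path) {
  ok <- tryCatch({
    if (inherits(res, "circuit_trajectory")) {
      write_trajectory(res, path)
    } else if (inherits(res, "step_response")) {
      write_trajectory(res$trajectory, path)
    } else if (inherits(res, "qic_report")) {
      write_qic_report(res, path)
    } else if (inherits(res, "robustness_result")) {
      jsonlite::write_json(unclass(res), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    } else {
      write_sweep(res, path)
    }
    TRUE
  }, error = function(e) {
    stop(errorCondition(paste0("failed to write ", path, ": ",
                               conditionMessage(e)),
                        class = c("io_error", "error")))
  })
  invisible(ok)
}
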