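#' Read and validate a run configuration
#'
#' A run configuration is one flat YAML file wiring the pipeline together:
#' the receptor calibration, an adaptation model name plus overrides, a
#' stimulus protocol, a FRET calibration, integrator tolerances, a seed and
#' output settings. Schema violations are reported field by field; an
#' unknown model name lists the registry.
#'
#' Layout (all sections optional except `model` and `protocol`):
#' ```yaml
#' seed: 1
#' model: {name: power-h3, a: 0.3333, g_R: 0.0069, imprecise: false}
#' protocol:
#'   ambient: 0.1
#'   k_rise: 1.0
#'   k_fall: 1.3
#'   t_end: 600
#'   events: [{time: 5, kind: ADD, delta: 0.1}]
#' noise_sd: 0.05
#' strain: WT1
#' collapse: {onset_delay: 10, window: 20}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A validated list of class `chemo_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  errors <- character(0)
  if (is.null(cfg$model) || is.null(cfg$model$name)) {
    errors <- c(errors, "model.name: required")
  } else if (!cfg$model$name %in% adaptation_models()) {
    errors <- c(errors, sprintf(
      "model.name: unknown model '%s'; registry: %s",
      cfg$model$name, paste(adaptation_models(), collapse = ", ")
    ))
  }
  if (is.null(cfg$protocol)) {
    errors <- c(errors, "protocol: required")
  } else {
    if (is.null(cfg$protocol$ambient) || cfg$protocol$ambient < 0) {
      errors <- c(errors, "protocol.ambient: required non-negative number")
    }
    for (ev in cfg$protocol$events %||% list()) {
      if (is.null(ev$time) || is.null(ev$kind) || is.null(ev$delta) ||
        !ev$kind %in% c("ADD", "REMOVE")) {
        errors <- c(errors, "protocol.events: each event needs time, kind (ADD|REMOVE), delta")
        break
      }
    }
  }
  if (!is.null(cfg$noise_sd) && cfg$noise_sd < 0) errors <- c(errors, "noise_sd: must be >= 0")
  if (!is.null(cfg$strain) && !cfg$strain %in% c("WT1", "WT2", "CHEB_MUTANT")) {
    errors <- c(errors, "strain: must be WT1, WT2 or CHEB_MUTANT")
  }
  if (length(errors)) {
    abort(c("invalid run configuration", setNames(errors, rep("x", length(errors)))))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "chemo_run_config")
}

# Materialise config pieces.
config_protocol <- function(cfg) {
  ev <- dplyr::bind_rows(lapply(cfg$protocol$events %||% list(), tibble::as_tibble))
  if (nrow(ev) == 0) ev <- NULL
  step_protocol(
    cfg$protocol$ambient, ev,
    cfg$protocol$k_rise %||% Inf, cfg$protocol$k_fall %||% Inf,
    cfg$protocol$t_end %||% 600
  )
}

config_model <- function(cfg) {
  m <- cfg$model
  adaptation_model(m$name,
    a = m$a %||% 1 / 3, g_R = m$g_R %||% 0.0069,
    g_B = m$g_B, K_R = m$K_R %||% 0.1, K_B = m$K_B %||% 0.1,
    imprecise = isTRUE(m$imprecise)
  )
}

#' Run a pipeline task from a configuration
#'
#' Single entry point over the package's analyses. Tasks:
#' `"simulate"` (activity time course), `"dose-response"`,
#' `"collapse"` (extract the data collapse of the simulated course),
#' `"fit"` (collapse + one-parameter model fit),
#' `"synth"` (synthetic FRET experiment), `"permtest"` (self-test of the
#' permutation machinery on the configured experiment against its own
#' model). Outputs are written as delimited text with a provenance header
#' (configuration hash, seed, package version) when `out` is given; the
#' result object is returned invisibly either way. Identical configuration
#' and seed give byte-identical outputs.
#'
#' @param cfg A `chemo_run_config` from [read_run_config()].
#' @param task Task name, see above.
#' @param out Optional output file path.
#' @param params Receptor parameters (default: shipped calibration).
#' @return The computed object, invisibly.
#' @export
run_analysis <- function(cfg, task = c("simulate", "dose-response", "collapse",
                                       "fit", "synth", "permtest"),
                         out = NULL, params = default_receptor_params()) {
  task <- match.arg(task)
  spec <- config_model(cfg)
  protocol <- config_protocol(cfg)
  meta <- c(
    config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
    chemodyn = as.character(utils::packageVersion("chemodyn")), task = task
  )
  result <- switch(task,
    "simulate" = simulate_timecourse(protocol, params, spec),
    "dose-response" = dose_response(
      cfg$dose$ambients %||% protocol$L_ambient,
      cfg$dose$deltas %||% c(0.03, 0.05, 0.1, 0.4, 2),
      params, spec,
      k_rise = protocol$k_rise, k_fall = protocol$k_fall
    ),
    "collapse" = extract_collapse(
      simulate_timecourse(protocol, params, spec),
      onset_delay = cfg$collapse$onset_delay %||% 10,
      window = cfg$collapse$window %||% 20
    ),
    "fit" = {
      cs <- extract_collapse(
        simulate_timecourse(protocol, params, spec),
        onset_delay = cfg$collapse$onset_delay %||% 10,
        window = cfg$collapse$window %||% 20
      )
      fit_gR(cs, model = spec$name, a = spec$a)
    },
    "synth" = {
      sx <- synthetic_experiment(cfg$strain %||% "WT1", protocol,
        noise_sd = cfg$noise_sd %||% 0.05, seed = cfg$seed,
        spec = spec, keep_flow = TRUE
      )
      generate_fret_experiment(sx, params)
    },
    "permtest" = {
      cs <- extract_collapse(
        simulate_timecourse(protocol, params, spec),
        onset_delay = cfg$collapse$onset_delay %||% 10,
        window = cfg$collapse$window %||% 20
      )
      curve <- collapse_curve(spec, params,
        N = complex_size(protocol$L_ambient, params), normalized = TRUE
      )
      permutation_test(cs, cs, curve, curve,
        n_pairs = cfg$permtest$n_pairs %||% 4,
        n_permutations = cfg$permtest$n_permutations %||% 100,
        seed = cfg$seed
      )
    }
  )
  if (!is.null(out)) {
    tab <- switch(task,
      "simulate" = , "collapse" = , "dose-response" = tibble::as_tibble(result),
      "fit" = tidy(result),
      "synth" = result$ratio,
      "permtest" = tibble::tibble(error = c(result$unpermuted_error, result$permuted_errors),
        kind = c("unpermuted", rep("permuted", result$n_permutations))
      )
    )
    write_chemo_table(tab, out, meta)
  }
  invisible(result)
}
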