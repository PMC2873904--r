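#' Strain presets for synthetic experiments
#'
#' Bundles the study conditions of the three strains the analyses emulate:
#'
#' * `WT1` — adapted activity 1/3, 0.2 s sampling, fast flow, cooperative
#'   CheB feedback (`power-h3`).
#' * `WT2` — CheB expressed at a reduced level: adapted activity 1/2, 1 s
#'   sampling, slower flow, `power-h3`.
#' * `CHEB_MUTANT` — non-regulatable CheB with matched kinase activity:
#'   adapted activity 1/2, 1 s sampling, slower flow, `cheb-mutant` kinetics.
#'
#' Rate constants and calibration come from the shipped configuration.
#'
#' @param strain `"WT1"`, `"WT2"` or `"CHEB_MUTANT"`.
#' @param path Optional alternative YAML configuration.
#' @return A list with elements `a`, `dt_sample`, `flow`, `model_name`,
#'   `g_R`, `alpha`.
#' @export
strain_preset <- function(strain = c("WT1", "WT2", "CHEB_MUTANT"),
                          path = chemodyn_config_path()) {
  strain <- match.arg(strain)
  cfg <- chemodyn_config(path)
  ad <- cfg$adaptation
  list(
    strain = strain,
    a = if (strain == "WT1") ad$a_wt1 else ad$a_wt2,
    dt_sample = if (strain == "WT1") cfg$fret$dt_wt1 else cfg$fret$dt_wt2,
    flow = default_flow(strain, path),
    model_name = if (strain == "CHEB_MUTANT") "cheb-mutant" else "power-h3",
    g_R = ad$g_R,
    alpha = cfg$fret$alpha
  )
}

#' Specify a synthetic FRET experiment
#'
#' Describes one in-silico flow-chamber experiment: a strain preset fixing
#' the adapted activity, sampling resolution, flow constants and adaptation
#' model; a stimulus protocol; additive Gaussian measurement noise on the
#' normalized activity; and a seed making the generated data reproducible.
#'
#' @param strain Strain preset name (see [strain_preset()]).
#' @param protocol A [step_protocol()]; its flow rate constants are replaced
#'   by the preset's unless `keep_flow = TRUE`.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   normalized activity (`>= 0`).
#' @param seed Integer RNG seed.
#' @param calib A [fret_calibration()]; default uses the preset's `alpha`
#'   and sampling resolution.
#' @param spec Adaptation model override; default built from the preset.
#' @param imprecise Generate with the imprecise-adaptation variant.
#' @param keep_flow Keep the protocol's own flow constants.
#' @param method FRET transform used to emit ratios (see
#'   [activity_to_ratio()]).
#' @return A list of class `synthetic_experiment`.
#' @export
synthetic_experiment <- function(strain = "WT1", protocol, noise_sd = 0.05,
                                 seed = 1, calib = NULL, spec = NULL,
                                 imprecise = FALSE, keep_flow = FALSE,
                                 method = "linear") {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  preset <- strain_preset(strain)
  if (!keep_flow) {
    protocol <- step_protocol(
      protocol$L_ambient, protocol$events,
      preset$flow$k_rise, preset$flow$k_fall, protocol$t_end
    )
  }
  if (is.null(spec)) {
    spec <- adaptation_model(preset$model_name,
      a = preset$a, g_R = preset$g_R,
      imprecise = imprecise
    )
  }
  calib <- calib %||% fret_calibration(alpha = preset$alpha, dt_sample = preset$dt_sample)
  structure(
    list(
      strain = strain, preset = preset, protocol = protocol, spec = spec,
      noise_sd = noise_sd, seed = as.integer(seed), calib = calib,
      method = method
    ),
    class = "synthetic_experiment"
  )
}

#' Generate a synthetic FRET experiment
#'
#' Simulates the configured model under the experiment's protocol, samples
#' the normalized activity at the strain's resolution, adds i.i.d. Gaussian
#' measurement noise, and applies the inverse FRET transform to emit an
#' intensity-ratio series. The noiseless ground-truth time course is always
#' returned alongside, so recovery of generating parameters can be scored.
#'
#' The same seed reproduces the output exactly; `truth` may be supplied to
#' reuse a previously simulated ground truth when drawing many noise
#' realisations of one experiment.
#'
#' @param sx A [synthetic_experiment()].
#' @param params Receptor parameters (default: shipped calibration).
#' @param truth Optional precomputed ground-truth time course for this
#'   experiment.
#' @return A list with elements `ratio` (tibble `t`, `R`), `activity`
#'   (tibble `t`, `A_norm`, noisy), `truth` (a `chemo_timecourse`) and the
#'   generating `spec` and `calib`.
#' @export
generate_fret_experiment <- function(sx, params = default_receptor_params(),
                                     truth = NULL) {
  if (is.null(truth)) {
    truth <- simulate_timecourse(sx$protocol, params, sx$spec,
      dt = sx$calib$dt_sample
    )
  }
  dt <- sx$calib$dt_sample
  on_grid <- abs(truth$t / dt - round(truth$t / dt)) < 1e-9
  sampled <- truth[on_grid, ]
  noisy <- with_seed(sx$seed, {
    sampled$A_norm + rnorm(nrow(sampled), sd = sx$noise_sd)
  })
  noisy <- pmax(noisy, 0) # a photon-count readout cannot go below saturation
  act <- tibble::tibble(t = sampled$t, A_norm = noisy)
  list(
    ratio = activity_to_ratio(act, sx$calib, method = sx$method),
    activity = act,
    truth = truth,
    spec = sx$spec,
    calib = sx$calib
  )
}

#' Collapse set of a measured (or synthetic) normalized-activity series
#'
#' Runs the collapse extraction on a noisy normalized-activity series (for
#' instance the output of [ratio_to_activity()] applied to FRET data),
#' attaching the protocol and model context needed downstream. The absolute
#' activity is reconstructed as `a * A_norm`.
#'
#' @param act Tibble with columns `t` and `A_norm`.
#' @param protocol The [step_protocol()] of the recording.
#' @param a Adapted pre-stimulus activity of the strain.
#' @param params Receptor parameters.
#' @param N Complex size (default: at the protocol ambient).
#' @inheritParams extract_collapse
#' @return A `chemo_collapse` tibble.
#' @export
collapse_from_activity <- function(act, protocol, a, params,
                                   N = complex_size(protocol$L_ambient, params),
                                   onset_delay = 10, window = 20,
                                   pairing = c("midpoint", "left")) {
  tc <- tibble::tibble(
    t = act$t, L = protocol_concentration(protocol, act$t),
    m = NA_real_, A = pmin(pmax(a * act$A_norm, 0), 1), A_norm = act$A_norm
  )
  tc <- structure(tc,
    class = c("chemo_timecourse", class(tc)),
    protocol = protocol, spec = NULL, params = params, N = N, A0 = a
  )
  extract_collapse(tc, onset_delay = onset_delay, window = window, pairing = match.arg(pairing))
}

#' Step-protocol campaign of an adaptation experiment
#'
#' Builds one add-then-adapt-then-remove protocol per step size, all at one
#' ambient concentration — the protocol family behind the dose-response and
#' data-collapse analyses (reference step sizes 0.03, 0.05, 0.1, 0.4 and
#' 2 mM at 0.1 mM ambient).
#'
#' @param L_ambient Ambient concentration, mM.
#' @param deltas Step sizes, mM.
#' @param t_add,t_remove Event times, s (the gap must allow re-adaptation).
#' @param t_end Protocol end, s.
#' @param k_rise,k_fall Flow rate constants, 1/s.
#' @return A list of [step_protocol()]s, one per step size.
#' @export
campaign_protocols <- function(L_ambient = 0.1,
                               deltas = c(0.03, 0.05, 0.1, 0.4, 2),
                               t_add = 20, t_remove = 520, t_end = 800,
                               k_rise = Inf, k_fall = Inf) {
  lapply(deltas, function(d) {
    step_protocol(
      L_ambient,
      tibble::tibble(time = c(t_add, t_remove), kind = c("ADD", "REMOVE"), delta = d),
      k_rise, k_fall, t_end
    )
  })
}
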