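#' Parameters of mixed Tar/Tsr receptor complexes
#'
#' Bundles the constants of the static MWC description of a mixed chemoreceptor
#' complex: the Tar/Tsr composition, the MeAsp dissociation constants of each
#' receptor type in its on and off state, the linear per-dimer methylation free
#' energy \eqn{f(m) = f_0 + f_1 m} (kT), and the linear map from ambient
#' attractant concentration to complex size \eqn{N(L_0) = N_0 + c L_0}.
#'
#' Attractant binding favours the off (inactive) state, so each `K_off` must be
#' smaller than the matching `K_on`; methylation favours the on state, so
#' `fm_slope` must be negative.
#'
#' @param nu_a,nu_s Fractions of Tar and Tsr dimers per complex (must sum to 1).
#' @param K_off_a,K_on_a MeAsp dissociation constants of Tar in the off/on
#'   state, mM.
#' @param K_off_s,K_on_s Same for Tsr, mM.
#' @param fm_intercept,fm_slope Coefficients of the per-dimer methylation free
#'   energy, kT and kT per methyl group.
#' @param size_intercept,size_slope Coefficients of the complex-size map,
#'   dimers and dimers/mM.
#'
#' @return An object of class `receptor_params`.
#' @seealso [default_receptor_params()] for the shipped reference calibration.
#' @export
receptor_params <- function(nu_a, nu_s, K_off_a, K_on_a, K_off_s, K_on_s,
                            fm_intercept, fm_slope,
                            size_intercept, size_slope) {
  p <- list(
    nu_a = nu_a, nu_s = nu_s,
    K_off_a = K_off_a, K_on_a = K_on_a,
    K_off_s = K_off_s, K_on_s = K_on_s,
    fm_intercept = fm_intercept, fm_slope = fm_slope,
    size_intercept = size_intercept, size_slope = size_slope
  )
  ks <- c(p$K_off_a, p$K_on_a, p$K_off_s, p$K_on_s)
  if (any(!is.finite(unlist(p[1:8]))) || any(ks <= 0)) {
    abort("all dissociation constants must be finite and positive")
  }
  if (p$K_off_a >= p$K_on_a || p$K_off_s >= p$K_on_s) {
    abort("K_off must be smaller than K_on for an attractant")
  }
  if (p$nu_a < 0 || p$nu_a > 1 || abs(p$nu_a + p$nu_s - 1) > 1e-6) {
    abort("nu_a must lie in [0, 1] and nu_a + nu_s must equal 1")
  }
  if (p$fm_slope >= 0) abort("fm_slope must be negative (methylation favours the on state)")
  if (p$size_intercept < 1) abort("complex size at zero ambient must be at least 1 dimer")
  structure(p, class = "receptor_params")
}

#' Reference receptor-complex calibration
#'
#' Reads the receptor constants shipped with the package
#' (`inst/extdata/chemodyn-params.yaml`), or from a user-supplied YAML file
#' with the same layout. All model constants are configuration, not code.
#'
#' @param path Path to a YAML configuration file; default is the shipped one.
#' @return A `receptor_params` object.
#' @export
default_receptor_params <- function(path = chemodyn_config_path()) {
  cfg <- yaml::read_yaml(path)$receptor
  do.call(receptor_params, cfg)
}

#' Path to the shipped model configuration
#' @return File path of the reference YAML configuration.
#' @export
chemodyn_config_path <- function() {
  system.file("extdata", "chemodyn-params.yaml", package = "chemodyn", mustWork = TRUE)
}

# Full shipped configuration as a list (receptor, adaptation, flow, fret).
chemodyn_config <- function(path = chemodyn_config_path()) yaml::read_yaml(path)

#' Methylation contribution to the complex free energy
#'
#' Per-dimer free energy from methylation, \eqn{f(m) = f_0 + f_1 m} in kT,
#' strictly decreasing in the methylation level `m` (methylation stabilises
#' the on state).
#'
#' @param m Methylation level per receptor dimer (methyl groups, `>= 0`).
#' @param params A [receptor_params()] object.
#' @return Free energy per dimer, kT.
#' @export
methylation_energy <- function(m, params) {
  if (any(m < 0)) abort("methylation level m must be non-negative")
  params$fm_intercept + params$fm_slope * m
}

#' Complex size at an ambient concentration
#'
#' Linear map \eqn{N(L_0) = N_0 + c L_0} from the ambient MeAsp concentration
#' the cells are adapted to, to the number of receptor dimers per signalling
#' complex. `N` is used as a continuous positive real (it enters the free
#' energy multiplicatively and is itself a least-squares fit).
#'
#' @param L_ambient Ambient MeAsp concentration, mM (`>= 0`).
#' @param params A [receptor_params()] object.
#' @return Complex size in dimers.
#' @export
complex_size <- function(L_ambient, params) {
  if (any(L_ambient < 0)) abort("ambient concentration must be non-negative")
  params$size_intercept + params$size_slope * L_ambient
}

# Per-dimer ligand free-energy term; >= 0 for attractant (K_off < K_on).
ligand_energy <- function(L, params) {
  params$nu_a * log((1 + L / params$K_off_a) / (1 + L / params$K_on_a)) +
    params$nu_s * log((1 + L / params$K_off_s) / (1 + L / params$K_on_s))
}

#' Free-energy difference of a receptor complex
#'
#' On/off free-energy difference of a complex of `N` dimers,
#' \deqn{F = N [ f(m) + \nu_a \ln\frac{1+L/K^{off}_a}{1+L/K^{on}_a}
#'                     + \nu_s \ln\frac{1+L/K^{off}_s}{1+L/K^{on}_s} ],}
#' in kT. The ligand term is non-negative for an attractant, so `F` increases
#' with `L` at fixed `m`; the methylation term decreases `F`.
#'
#' @param m Methylation level per dimer (methyl groups).
#' @param L MeAsp concentration, mM (`>= 0`).
#' @param params A [receptor_params()] object.
#' @param N Complex size in dimers (default: size at ambient `L`).
#' @return Free-energy difference, kT.
#' @export
free_energy <- function(m, L, params, N = complex_size(L, params)) {
  if (any(L < 0)) abort("ligand concentration must be non-negative")
  if (any(N < 1)) abort("complex size must be at least 1 dimer")
  N * (methylation_energy(m, params) + ligand_energy(L, params))
}

#' Activity of a two-state complex
#'
#' Probability of the on state, \eqn{A = 1/(1 + e^{F})}, strictly decreasing in
#' the free-energy difference `F`. Exponents are clamped at `|F| > 700` and the
#' exact 0/1 limits returned, so extreme energies cannot overflow.
#'
#' @param F Free-energy difference in kT (finite).
#' @return Activity in `[0, 1]`.
#' @export
activity <- function(F) {
  if (any(!is.finite(F))) abort("free energy must be finite")
  Fc <- pmin(pmax(F, -700), 700)
  1 / (1 + exp(Fc))
}

#' Complex activity at a given state
#'
#' Convenience composition `activity(free_energy(m, L, ...))`.
#'
#' @inheritParams free_energy
#' @return Activity in `[0, 1]`.
#' @export
receptor_activity <- function(m, L, params, N = complex_size(L, params)) {
  activity(free_energy(m, L, params, N))
}

#' Derivative of activity with respect to methylation level
#'
#' Analytic \eqn{\partial A/\partial m = -A(1-A) N f_1}, per methyl group.
#' Positive, since the methylation slope \eqn{f_1} is negative; vanishes at
#' saturated activity and is maximal at \eqn{A = 1/2}.
#'
#' @inheritParams free_energy
#' @return Derivative, per methyl group.
#' @export
d_activity_dm <- function(m, L, params, N = complex_size(L, params)) {
  A <- receptor_activity(m, L, params, N)
  dA_dm_at_A(A, N, params)
}

# dA/dm expressed through the activity itself (used on collapse data).
dA_dm_at_A <- function(A, N, params) {
  -A * (1 - A) * N * params$fm_slope
}

#' Derivative of activity with respect to ligand concentration
#'
#' Analytic \eqn{\partial A/\partial L = -A(1-A) N \, \partial f_L/\partial L},
#' per mM; negative for all `L >= 0` with attractant-ordered dissociation
#' constants.
#'
#' @inheritParams free_energy
#' @return Derivative, per mM.
#' @export
d_activity_dL <- function(m, L, params, N = complex_size(L, params)) {
  A <- receptor_activity(m, L, params, N)
  dfl <- params$nu_a * (1 / (params$K_off_a + L) - 1 / (params$K_on_a + L)) +
    params$nu_s * (1 / (params$K_off_s + L) - 1 / (params$K_on_s + L))
  -A * (1 - A) * N * dfl
}

#' @export
print.receptor_params <- function(x, ...) {
  cat("<receptor_params>\n")
  cat(sprintf("  Tar:Tsr fractions     %.4f : %.4f\n", x$nu_a, x$nu_s))
  cat(sprintf("  Tar K_off/K_on [mM]   %g / %g\n", x$K_off_a, x$K_on_a))
  cat(sprintf("  Tsr K_off/K_on [mM]   %g / %g\n", x$K_off_s, x$K_on_s))
  cat(sprintf("  f(m) [kT]             %g %+g m\n", x$fm_intercept, x$fm_slope))
  cat(sprintf("  N(L0) [dimers]        %g %+g L0\n", x$size_intercept, x$size_slope))
  invisible(x)
}
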