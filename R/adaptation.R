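#' Registry of adaptation models
#'
#' Names of the methylation/demethylation kinetic models known to
#' [adaptation_model()]:
#'
#' * `"power-h3"` — methylation \eqn{g_R(1-A)}, demethylation \eqn{g_B A^3}
#'   (CheB binding to active receptors with cooperative CheB-P feedback; the
#'   headline model).
#' * `"power-h2"` — demethylation \eqn{g_B A^2} (linear CheB-P feedback).
#' * `"power-h1"` — demethylation \eqn{g_B A} (no CheB-P feedback).
#' * `"mm-feedback"` — Michaelis–Menten kinetics
#'   \eqn{g_R(1-A)/(K_R+1-A) - g_B A\cdot A/(K_B+A)} (linear CheB feedback).
#' * `"mm-nofeedback"` — \eqn{g_R(1-A)/(K_R+1-A) - g_B A/(K_B+A)}.
#' * `"cheb-mutant"` — \eqn{g_R(1-A) - g_B A}: non-regulatable CheB, the only
#'   activity dependence of demethylation is CheB binding to active receptors.
#'
#' @return Character vector of registry names.
#' @export
adaptation_models <- function() {
  c("power-h3", "power-h2", "power-h1", "mm-feedback", "mm-nofeedback", "cheb-mutant")
}

#' Construct an adaptation model
#'
#' One member of the methylation/demethylation kinetic family (see
#' [adaptation_models()]), holding its rate constants and, optionally, the
#' imprecise-adaptation site-availability factors. Unless supplied, the
#' demethylation constant `g_B` is set by [solve_gB()] so that the kinetics
#' balance at the adapted activity `a`.
#'
#' @param name Registry name, see [adaptation_models()].
#' @param a Adapted (steady-state) activity in `(0, 1)`.
#' @param g_R Methylation rate constant, methyl groups/s.
#' @param g_B Demethylation rate constant, methyl groups/s; default solved
#'   from the steady-state condition at `a`.
#' @param K_R,K_B Michaelis constants (activity units), used by the `mm-*`
#'   models only.
#' @param imprecise Logical; enable methylation-site saturation (see
#'   [dm_dt()]).
#' @param M_max Maximum average methyl groups per dimer available to the
#'   complex (imprecise model).
#' @param m_c Number of available/occupied sites below which methylation or
#'   demethylation becomes inefficient (imprecise model), `0 <= m_c < M_max`.
#' @return An object of class `adaptation_model`.
#' @export
adaptation_model <- function(name = "power-h3", a = 1 / 3, g_R = 0.0069,
                             g_B = NULL, K_R = 0.1, K_B = 0.1,
                             imprecise = FALSE, M_max = 8 * 0.4166666666666667,
                             m_c = 0.5) {
  if (!name %in% adaptation_models()) {
    abort(sprintf(
      "unknown adaptation model '%s'; registry: %s",
      name, paste(adaptation_models(), collapse = ", ")
    ))
  }
  if (!(a > 0 && a < 1)) abort("adapted activity a must lie strictly in (0, 1)")
  if (g_R <= 0) abort("g_R must be positive")
  family <- if (startsWith(name, "power")) "POWER" else if (startsWith(name, "mm")) "MICHAELIS" else "CHEB_MUTANT"
  h <- switch(name, "power-h3" = 3L, "power-h2" = 2L, "power-h1" = 1L, 1L)
  mm_feedback <- identical(name, "mm-feedback")
  if (family == "MICHAELIS" && (K_R <= 0 || K_B <= 0)) abort("K_R and K_B must be positive")
  if (imprecise && !(m_c >= 0 && m_c < M_max)) abort("need 0 <= m_c < M_max for the imprecise model")
  spec <- structure(
    list(
      name = name, family = family, h = h, a = a, g_R = g_R, g_B = g_B,
      K_R = K_R, K_B = K_B, mm_feedback = mm_feedback,
      imprecise = imprecise, M_max = M_max, m_c = m_c
    ),
    class = "adaptation_model"
  )
  if (is.null(g_B)) spec$g_B <- solve_gB(g_R, a, spec)
  if (spec$g_B <= 0) abort("g_B must be positive")
  spec
}

# Activity-dependent methylation/demethylation shapes with unit rate constants.
meth_shape <- function(A, spec) {
  switch(spec$family,
    POWER = 1 - A,
    CHEB_MUTANT = 1 - A,
    MICHAELIS = (1 - A) / (spec$K_R + (1 - A))
  )
}

demeth_shape <- function(A, spec) {
  switch(spec$family,
    POWER = A^spec$h,
    CHEB_MUTANT = A,
    MICHAELIS = {
      base <- A / (spec$K_B + A)
      if (spec$mm_feedback) A * base else base
    }
  )
}

# Site-availability factors of the imprecise model: methylation needs free
# sites, demethylation needs occupied sites; efficiency degrades linearly
# below m_c available/occupied sites and never turns a rate negative.
site_factor <- function(x, m_c) pmin(pmax(x, 0) / m_c, 1)

#' Rate of change of the methylation level
#'
#' Kinetics of the average receptor methylation level per dimer:
#' receptors are methylated (CheR) in proportion to the inactive fraction and
#' demethylated (CheB-P) in proportion to an activity power or Michaelis term,
#' per the model family (see [adaptation_models()]). With `imprecise = TRUE`
#' both terms are additionally scaled by linear site-availability factors:
#' methylation by `min{1, (M_max - m)/m_c}` and demethylation by
#' `min{1, m/m_c}`, so rates shrink as modification sites saturate or empty
#' but never become negative.
#'
#' @param A Receptor-complex activity in `[0, 1]`.
#' @param m Methylation level (methyl groups per dimer); required when the
#'   model is imprecise, ignored otherwise.
#' @param spec An [adaptation_model()].
#' @return dm/dt in methyl groups per second.
#' @export
dm_dt <- function(A, m = NULL, spec) {
  if (any(A < 0 | A > 1)) abort("activity must lie in [0, 1]")
  meth <- spec$g_R * meth_shape(A, spec)
  demeth <- spec$g_B * demeth_shape(A, spec)
  if (spec$imprecise) {
    if (is.null(m)) abort("the imprecise model needs the methylation level m")
    if (any(m < 0)) abort("methylation level m must be non-negative")
    meth <- meth * site_factor(spec$M_max - m, spec$m_c)
    demeth <- demeth * site_factor(m, spec$m_c)
  }
  meth - demeth
}

#' Demethylation constant from the steady-state condition
#'
#' Returns the demethylation rate constant `g_B` for which the precise core of
#' the kinetics balances at the adapted activity, `dm/dt(a) = 0`. Closed form
#' for the power-law and CheB-mutant families; a one-dimensional root solve
#' for the Michaelis–Menten family. The site-availability factors of the
#' imprecise model are not part of the balance: the rate constants are shared
#' between the precise and imprecise variants, and the imprecise steady state
#' is found self-consistently by the simulator.
#'
#' @param g_R Methylation rate constant.
#' @param a Adapted activity in `(0, 1)`.
#' @param spec An [adaptation_model()] (its `g_B` is ignored).
#' @return The demethylation rate constant, methyl groups/s.
#' @export
solve_gB <- function(g_R, a, spec) {
  if (!(a > 0 && a < 1)) abort("no demethylation constant balances a degenerate adapted activity")
  if (spec$family %in% c("POWER", "CHEB_MUTANT")) {
    return(g_R * meth_shape(a, spec) / demeth_shape(a, spec))
  }
  target <- g_R * meth_shape(a, spec)
  f <- function(gB) target - gB * demeth_shape(a, spec)
  upper <- 2 * target / demeth_shape(a, spec) + 1
  uniroot(f, lower = 0, upper = upper, tol = 1e-14)$root
}

#' Adapted methylation level at an ambient concentration
#'
#' Inverts the MWC activity in the methylation level: the `m` at which the
#' complex activity equals the adapted activity `a` at concentration
#' `L_ambient`,
#' \deqn{m = \frac{\ln((1-a)/a)/N - f_L(L) - f_0}{f_1}.}
#'
#' @param L_ambient Ambient MeAsp concentration, mM.
#' @param a Adapted activity in `(0, 1)`.
#' @param params A [receptor_params()] object.
#' @param N Complex size (default: size at `L_ambient`).
#' @return The adapted methylation level (methyl groups per dimer). An error
#'   is raised if the required level is negative, which flags a model
#'   inconsistency at that ambient concentration.
#' @export
adapted_methylation <- function(L_ambient, a, params,
                                N = complex_size(L_ambient, params)) {
  if (!(all(a > 0) && all(a < 1))) abort("adapted activity must lie strictly in (0, 1)")
  m <- invert_methylation(L_ambient, a, params, N)
  if (any(m < 0)) {
    abort("adapted methylation level is negative: model inconsistent at this ambient concentration")
  }
  m
}

# Same inversion without the negativity guard (internal).
invert_methylation <- function(L_ambient, a, params, N) {
  (log((1 - a) / a) / N - ligand_energy(L_ambient, params) - params$fm_intercept) /
    params$fm_slope
}

#' Adaptation-only rate of activity change
#'
#' The data-collapse curve \eqn{g(A) = (\partial A/\partial m) \cdot dm/dt}:
#' the rate of activity change when the ligand concentration is constant and
#' all change comes from adaptation. For precise models this depends on the
#' activity (and the complex size at the ambient concentration) only; for the
#' imprecise model the methylation level consistent with `A` at `L_ambient`
#' is used in the site factors.
#'
#' @param A Activity in `[0, 1]` (vectorised).
#' @param spec An [adaptation_model()].
#' @param params A [receptor_params()] object.
#' @param L_ambient Ambient concentration setting the complex size, mM.
#' @param N Complex size override.
#' @return dA/dt in 1/s.
#' @export
collapse_rate <- function(A, spec, params, L_ambient = 0,
                          N = complex_size(L_ambient, params)) {
  if (any(A < 0 | A > 1)) abort("activity must lie in [0, 1]")
  m <- NULL
  if (spec$imprecise) {
    inner <- A > 0 & A < 1
    m <- rep(0, length(A)) # saturated activities: rate is zero through dA/dm anyway
    m[inner] <- pmax(invert_methylation(L_ambient, A[inner], params, N), 0)
  }
  dA_dm_at_A(A, N, params) * dm_dt(A, m, spec)
}

#' Fixed points of the adaptation-only dynamics
#'
#' Zeros of the collapse curve \eqn{g(A)} on `[0, 1]`, located by a sign-change
#' scan on a uniform grid followed by bisection polishing; duplicates within
#' `1e-8` are merged. For the precise power-law family the set is exactly
#' `{0, a, 1}`: saturated off, the adapted activity, saturated on.
#'
#' Imprecise models are refused: their fixed-point structure belongs to the
#' full two-variable (activity, methylation) system, not to a one-dimensional
#' activity flow.
#'
#' @param spec A precise [adaptation_model()].
#' @param params A [receptor_params()] object.
#' @param L_ambient Ambient concentration, mM.
#' @param grid_n Number of scan intervals (default `1e4`, i.e. spacing 1e-4).
#' @return Sorted numeric vector of fixed-point activities.
#' @export
fixed_points <- function(spec, params, L_ambient = 0, grid_n = 1e4) {
  if (spec$imprecise) {
    abort("fixed_points() is defined for precise models only; the imprecise fixed-point set lives in the (A, m) plane")
  }
  grid <- seq(0, 1, length.out = grid_n + 1)
  g <- collapse_rate(grid, spec, params, L_ambient)
  roots <- grid[g == 0]
  flips <- which(g[-1] * g[-length(g)] < 0)
  for (i in flips) {
    r <- uniroot(function(A) collapse_rate(A, spec, params, L_ambient),
      lower = grid[i], upper = grid[i + 1], tol = 1e-10
    )$root
    roots <- c(roots, r)
  }
  roots <- sort(roots)
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  roots
}

#' Collapse-curve function for a model
#'
#' Returns `g(A)` as a reusable function, optionally on the normalized scale
#' used for FRET comparisons (activity and rate both divided by the adapted
#' activity), where the fixed point sits at 1.
#'
#' @inheritParams collapse_rate
#' @param normalized Logical; if `TRUE` the returned function maps normalized
#'   activity `x = A/a` to `dA/dt / a`.
#' @return A function of one numeric argument.
#' @export
collapse_curve <- function(spec, params, L_ambient = 0,
                           N = complex_size(L_ambient, params),
                           normalized = FALSE) {
  force(spec); force(params); force(L_ambient); force(N)
  if (normalized) {
    function(x) collapse_rate(pmin(pmax(x * spec$a, 0), 1), spec, params, L_ambient, N) / spec$a
  } else {
    function(A) collapse_rate(A, spec, params, L_ambient, N)
  }
}

#' @export
print.adaptation_model <- function(x, ...) {
  cat(sprintf(
    "<adaptation_model> %s (a = %.4g, g_R = %.4g, g_B = %.4g%s)\n",
    x$name, x$a, x$g_R, x$g_B,
    if (x$imprecise) sprintf(", imprecise: M_max = %.3g, m_c = %.3g", x$M_max, x$m_c) else ""
  ))
  invisible(x)
}
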