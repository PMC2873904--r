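# Activity without the non-negativity guard on m: the integrator may probe
# tiny negative excursions; energies stay finite and clamped.
activity_raw <- function(m, L, params, N) {
  activity(N * (params$fm_intercept + params$fm_slope * m + ligand_energy(L, params)))
}

# Self-consistent steady state of the imprecise model at constant L:
# root of dm/dt(A(m), m) in m.
imprecise_steady_m <- function(L, spec, params, N) {
  f <- function(m) dm_dt(activity_raw(m, L, params, N), pmax(m, 0), spec)
  lo <- 0
  hi <- spec$M_max
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
}

#' Simulate an activity time course under a stimulus protocol
#'
#' Integrates the methylation kinetics `dm/dt` of an adaptation model with the
#' receptor-complex activity evaluated algebraically from the MWC free energy
#' at every step (the phosphorylation cascade downstream of the receptors is
#' in quasi-steady state, so complex activity stands in for the FRET readout).
#' The ligand concentration follows the protocol's piecewise-exponential
#' profile and the integration restarts at every protocol event.
#'
#' The initial condition is the adapted state at the ambient concentration:
#' the methylation level solving `activity = a` for precise models, or the
#' self-consistent steady state of the full (activity, methylation) system
#' for the imprecise model. The complex size is frozen at the value for the
#' concentration the cells start adapted to.
#'
#' @param protocol A [step_protocol()].
#' @param params A [receptor_params()] object.
#' @param spec An [adaptation_model()].
#' @param dt Output sampling resolution, s.
#' @param N Complex size, dimers; default: size at the protocol's ambient.
#' @param m0 Initial methylation level; default: adapted state (see above).
#' @param rtol,atol Relative/absolute integrator tolerances (stiff-capable
#'   adaptive `lsoda`).
#' @return A tibble of class `chemo_timecourse` with columns `t` (s), `L`
#'   (mM), `m` (methyl groups/dimer), `A` (activity) and `A_norm` (activity
#'   normalized by the pre-stimulus adapted value), carrying the protocol,
#'   model and parameters as attributes.
#' @export
simulate_timecourse <- function(protocol, params, spec, dt = 0.2,
                                N = complex_size(protocol$L_ambient, params),
                                m0 = NULL, rtol = 1e-8, atol = 1e-10) {
  if (is.null(m0)) {
    m0 <- if (spec$imprecise) {
      imprecise_steady_m(protocol$L_ambient, spec, params, N)
    } else {
      adapted_methylation(protocol$L_ambient, spec$a, params, N)
    }
  }
  bounds <- sort(unique(c(0, protocol$events$time, protocol$t_end)))
  grid <- sort(unique(c(seq(0, protocol$t_end, by = dt), bounds)))
  rhs <- function(t, y, parms) {
    t <- min(max(t, 0), protocol$t_end) # lsoda may probe slightly past a boundary
    A <- activity_raw(y[1], protocol_concentration(protocol, t), params, N)
    list(dm_dt(A, pmax(y[1], 0), spec))
  }
  t_out <- numeric(0)
  m_out <- numeric(0)
  m_cur <- m0
  for (i in seq_len(length(bounds) - 1)) {
    seg <- grid[grid >= bounds[i] & grid <= bounds[i + 1]]
    if (length(seg) < 2) seg <- c(bounds[i], bounds[i + 1])
    sol <- tryCatch(
      deSolve::ode(
        y = c(m = m_cur), times = seg, func = rhs, parms = NULL,
        method = "lsoda", rtol = rtol, atol = atol
      ),
      warning = function(w) abort(sprintf(
        "integration failed on segment [%g, %g] s: %s", bounds[i], bounds[i + 1], conditionMessage(w)
      ))
    )
    m_cur <- unname(sol[nrow(sol), 2])
    keep <- if (i == 1) seq_len(nrow(sol)) else -1L # segment starts duplicate event times
    t_out <- c(t_out, sol[keep, 1])
    m_out <- c(m_out, sol[keep, 2])
  }
  if (min(m_out) < -1e-6) {
    abort("methylation level left the physical range during integration")
  }
  m_out <- pmax(m_out, 0)
  L_out <- protocol_concentration(protocol, t_out)
  A_out <- receptor_activity(m_out, L_out, params, N)
  if (any(A_out < -1e-9 | A_out > 1 + 1e-9)) abort("activity left [0, 1] during integration")
  A0 <- A_out[1]
  tc <- tibble::tibble(t = t_out, L = L_out, m = m_out, A = A_out, A_norm = A_out / A0)
  structure(tc,
    class = c("chemo_timecourse", class(tc)),
    protocol = protocol, spec = spec, params = params, N = N, A0 = A0, dt = dt
  )
}

# Default post-event search window: 5 / (relevant flow rate constant),
# or 2 s for a perfect step.
response_window <- function(protocol, event_index) {
  kind <- protocol$events$kind[event_index]
  k <- if (kind == "ADD") protocol$k_rise else protocol$k_fall
  if (is.finite(k)) 5 / k else 2
}

#' Initial response amplitude from a time course
#'
#' Magnitude of the initial response to a protocol event: the largest
#' excursion of the normalized activity from its pre-stimulus value 1 within
#' a search window after the event (by default `5/k` of the relevant flow
#' rate constant, so the "initial" response precedes substantial adaptation).
#' The amplitude is reported non-negative; the direction of the stimulus is
#' metadata.
#'
#' @param tc A `chemo_timecourse` from [simulate_timecourse()].
#' @param event_index Which protocol event (default: first).
#' @param window Search window length, s (default, see above).
#' @return Non-negative normalized amplitude.
#' @export
initial_response <- function(tc, event_index = 1L, window = NULL) {
  protocol <- attr(tc, "protocol")
  if (event_index < 1 || event_index > nrow(protocol$events)) {
    abort("event_index outside the protocol's event list")
  }
  t_e <- protocol$events$time[event_index]
  window <- window %||% response_window(protocol, event_index)
  sel <- tc$t >= t_e & tc$t <= t_e + window
  if (!any(sel)) abort("empty post-event search window")
  max(abs(tc$A_norm[sel] - 1))
}

#' Halfway recovery time after a stimulus
#'
#' Time from a protocol event until the normalized activity has returned
#' halfway from its post-event extremum towards the pre-stimulus level 1.
#' Used to quantify the asymmetry between slow adaptation to added attractant
#' (methylation) and fast adaptation to removed attractant (demethylation).
#'
#' @inheritParams initial_response
#' @return Time, s (from the event instant).
#' @export
halfway_recovery_time <- function(tc, event_index = 1L) {
  protocol <- attr(tc, "protocol")
  t_e <- protocol$events$time[event_index]
  t_next <- if (event_index < nrow(protocol$events)) {
    protocol$events$time[event_index + 1]
  } else {
    protocol$t_end
  }
  sel <- which(tc$t >= t_e & tc$t < t_next) # next event instant belongs to the next segment
  dev <- abs(tc$A_norm[sel] - 1)
  i_ext <- which.max(dev)
  half <- dev[i_ext] / 2
  after <- sel[seq(i_ext, length(sel))]
  rec <- which(abs(tc$A_norm[after] - 1) <= half)
  if (!length(rec)) abort("activity does not recover halfway within the segment")
  tc$t[after[rec[1]]] - t_e
}

#' Closed-form initial response of the static MWC model
#'
#' Response amplitude to a perfect concentration step with the methylation
#' level frozen at its adapted value (no adaptation dynamics, no flow):
#' `|A(L_after, m_adapted)/a - 1|`. For removal points the cells are adapted
#' to the stepped-up concentration `L0 + delta`, including the complex size
#' interpolated at that concentration.
#'
#' @param L_ambient Ambient concentration the curve is indexed by, mM.
#' @param delta Step size, mM.
#' @param direction `"ADD"` or `"REMOVE"`.
#' @param params A [receptor_params()] object.
#' @param a Adapted activity.
#' @return Non-negative normalized amplitude.
#' @export
static_response <- function(L_ambient, delta, direction, params, a) {
  if (direction == "ADD") {
    N <- complex_size(L_ambient, params)
    m_a <- adapted_methylation(L_ambient, a, params, N)
    A <- receptor_activity(m_a, L_ambient + delta, params, N)
  } else {
    N <- complex_size(L_ambient + delta, params)
    m_a <- adapted_methylation(L_ambient + delta, a, params, N)
    A <- receptor_activity(m_a, L_ambient, params, N)
  }
  abs(A / a - 1)
}

#' Dose-response curves of the static and dynamic MWC models
#'
#' Initial response amplitudes for addition and removal of concentration
#' steps on a grid of ambient concentrations and step sizes. Each removal
#' point starts from the state adapted to the stepped-up concentration
#' (add-then-adapt-then-remove protocol), with the complex size interpolated
#' at that concentration. The dynamic model includes exponential ligand flow
#' and adaptation during the response; the static model is the closed-form
#' frozen-methylation response to a perfect step.
#'
#' @param ambients Ambient concentrations, mM.
#' @param deltas Step sizes, mM.
#' @param params A [receptor_params()] object.
#' @param spec An [adaptation_model()] (dynamic model only).
#' @param type `"dynamic"` or `"static"`.
#' @param directions Subset of `c("ADD", "REMOVE")`.
#' @param k_rise,k_fall Flow rate constants, 1/s (`Inf` = perfect steps).
#' @param dt Simulation output resolution, s (dynamic model).
#' @param pre_time Settling time before the event, s.
#' @return A tibble of class `chemo_doseresponse` with columns `L_ambient`,
#'   `delta`, `direction`, `response`, `model`.
#' @export
dose_response <- function(ambients, deltas, params, spec = NULL,
                          type = c("dynamic", "static"),
                          directions = c("ADD", "REMOVE"),
                          k_rise = Inf, k_fall = Inf,
                          dt = 0.02, pre_time = 5) {
  type <- match.arg(type)
  if (is.null(spec)) abort("an adaptation model is required (its adapted activity sets the pre-stimulus state)")
  grid <- tidyr::expand_grid(
    L_ambient = ambients, delta = deltas,
    direction = intersect(c("ADD", "REMOVE"), directions)
  )
  a <- spec$a
  resp <- purrr::pmap_dbl(grid, function(L_ambient, delta, direction) {
    if (type == "static") {
      return(static_response(L_ambient, delta, direction, params, a))
    }
    if (direction == "ADD") {
      start_L <- L_ambient
      ev <- tibble::tibble(time = pre_time, kind = "ADD", delta = delta)
    } else {
      start_L <- L_ambient + delta
      ev <- tibble::tibble(time = pre_time, kind = "REMOVE", delta = delta)
    }
    k <- if (direction == "ADD") k_rise else k_fall
    window <- if (is.finite(k)) 5 / k else 2
    prot <- step_protocol(start_L, ev, k_rise, k_fall, t_end = pre_time + 1.5 * window)
    tc <- simulate_timecourse(prot, params, spec, dt = dt)
    initial_response(tc, 1L, window = window)
  })
  out <- dplyr::mutate(grid, response = resp, model = toupper(type))
  structure(out, class = c("chemo_doseresponse", class(out)))
}

#' Squared error between two dose-response curves
#'
#' Sum of squared differences of normalized response amplitudes over a
#' matched grid of (ambient, step size, direction) points.
#'
#' @param curve_a,curve_b Tibbles with columns `L_ambient`, `delta`,
#'   `direction`, `response` on identical grids.
#' @return Dimensionless squared error.
#' @export
squared_error <- function(curve_a, curve_b) {
  key <- c("L_ambient", "delta", "direction")
  joined <- dplyr::inner_join(curve_a, curve_b, by = key, suffix = c("_a", "_b"))
  if (nrow(joined) != nrow(curve_a) || nrow(joined) != nrow(curve_b)) {
    abort("dose-response grids do not match")
  }
  sum((joined$response_a - joined$response_b)^2)
}
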