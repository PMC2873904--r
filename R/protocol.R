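#' Step-stimulus protocol for the flow chamber
#'
#' Describes the time-dependent MeAsp concentration seen by tethered cells:
#' a constant ambient concentration plus timed addition/removal events. After
#' each event the concentration relaxes exponentially from its current value
#' towards the new target (ambient plus cumulative step changes), with rate
#' `k_rise` after an addition and `k_fall` after a removal — matching how
#' concentration changes establish over several seconds in a flow chamber.
#' `k = Inf` gives a perfect (instantaneous) step; the value at an event
#' instant follows the right-continuous convention.
#'
#' @param L_ambient Ambient concentration, mM (`>= 0`).
#' @param events A data frame with columns `time` (s, strictly increasing),
#'   `kind` (`"ADD"` or `"REMOVE"`) and `delta` (step magnitude, mM, `> 0`).
#'   May be empty.
#' @param k_rise,k_fall Exponential rate constants, 1/s (`Inf` allowed).
#' @param t_end End of the protocol window, s.
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(L_ambient, events = NULL, k_rise = Inf, k_fall = Inf,
                          t_end = 600) {
  if (L_ambient < 0) abort("ambient concentration must be non-negative")
  if (k_rise <= 0 || k_fall <= 0) abort("flow rate constants must be positive (Inf = perfect step)")
  if (is.null(events)) {
    events <- tibble::tibble(time = numeric(), kind = character(), delta = numeric())
  }
  events <- tibble::as_tibble(events)[, c("time", "kind", "delta")]
  if (nrow(events)) {
    if (any(diff(events$time) <= 0)) abort("event times must be strictly increasing")
    if (!all(events$kind %in% c("ADD", "REMOVE"))) abort("event kind must be ADD or REMOVE")
    if (any(events$delta <= 0)) abort("event step sizes must be positive")
    if (any(events$time < 0) || any(events$time > t_end)) abort("event times must lie in [0, t_end]")
  }
  sign <- ifelse(events$kind == "ADD", 1, -1)
  targets <- L_ambient + cumsum(sign * events$delta)
  if (any(targets < -1e-12)) abort("protocol would drive the concentration negative")
  structure(
    list(
      L_ambient = L_ambient, events = events, targets = pmax(targets, 0),
      k_rise = k_rise, k_fall = k_fall, t_end = t_end
    ),
    class = "step_protocol"
  )
}

#' Append an addition / removal event to a protocol
#'
#' @param protocol A [step_protocol()].
#' @param time Event time, s.
#' @param delta Step magnitude, mM.
#' @return The extended protocol.
#' @export
protocol_add <- function(protocol, time, delta) {
  ev <- dplyr::bind_rows(protocol$events, tibble::tibble(time = time, kind = "ADD", delta = delta))
  step_protocol(protocol$L_ambient, ev, protocol$k_rise, protocol$k_fall, protocol$t_end)
}

#' @rdname protocol_add
#' @export
protocol_remove <- function(protocol, time, delta) {
  ev <- dplyr::bind_rows(protocol$events, tibble::tibble(time = time, kind = "REMOVE", delta = delta))
  step_protocol(protocol$L_ambient, ev, protocol$k_rise, protocol$k_fall, protocol$t_end)
}

# Concentration at the start of each inter-event segment (exact recursion).
segment_starts <- function(protocol) {
  ev <- protocol$events
  n <- nrow(ev)
  L_at_event <- numeric(n) # concentration just before/at each event time
  L_prev <- protocol$L_ambient
  t_prev <- 0
  target_prev <- protocol$L_ambient
  k_prev <- Inf
  for (i in seq_len(n)) {
    dt <- ev$time[i] - t_prev
    L_at_event[i] <- if (is.finite(k_prev)) {
      target_prev + (L_prev - target_prev) * exp(-k_prev * dt)
    } else {
      target_prev
    }
    L_prev <- L_at_event[i]
    t_prev <- ev$time[i]
    target_prev <- protocol$targets[i]
    k_prev <- if (ev$kind[i] == "ADD") protocol$k_rise else protocol$k_fall
  }
  L_at_event
}

# Segment lookup: index of last event at or before t (0 = before all events).
segment_index <- function(protocol, t) {
  findInterval(t, protocol$events$time)
}

#' Concentration of a protocol at given times
#'
#' Piecewise-exponential MeAsp concentration (see [step_protocol()]);
#' continuous in `t`, right-continuous at event instants when a rate constant
#' is infinite.
#'
#' @param protocol A [step_protocol()].
#' @param t Times in `[0, t_end]`, s (vectorised).
#' @return Concentrations, mM.
#' @export
protocol_concentration <- function(protocol, t) {
  if (any(t < 0 | t > protocol$t_end)) abort("time outside the protocol window")
  n <- nrow(protocol$events)
  if (n == 0) return(rep(protocol$L_ambient, length(t)))
  starts <- segment_starts(protocol)
  idx <- segment_index(protocol, t)
  out <- numeric(length(t))
  pre <- idx == 0
  out[pre] <- protocol$L_ambient
  for (i in seq_len(n)) {
    sel <- idx == i
    if (!any(sel)) next
    k <- if (protocol$events$kind[i] == "ADD") protocol$k_rise else protocol$k_fall
    target <- protocol$targets[i]
    out[sel] <- if (is.finite(k)) {
      target + (starts[i] - target) * exp(-k * (t[sel] - protocol$events$time[i]))
    } else {
      target
    }
  }
  out
}

#' Rate of change of the protocol concentration
#'
#' Analytic time derivative of [protocol_concentration()]; zero between fully
#' relaxed events and for perfect steps, with the right-derivative convention
#' at event instants. Just after an addition of size `delta` from a relaxed
#' state it equals `k_rise * delta`.
#'
#' @inheritParams protocol_concentration
#' @return Derivatives, mM/s.
#' @export
protocol_dLdt <- function(protocol, t) {
  if (any(t < 0 | t > protocol$t_end)) abort("time outside the protocol window")
  n <- nrow(protocol$events)
  if (n == 0) return(rep(0, length(t)))
  starts <- segment_starts(protocol)
  idx <- segment_index(protocol, t)
  out <- numeric(length(t))
  for (i in seq_len(n)) {
    sel <- idx == i
    if (!any(sel)) next
    k <- if (protocol$events$kind[i] == "ADD") protocol$k_rise else protocol$k_fall
    target <- protocol$targets[i]
    out[sel] <- if (is.finite(k)) {
      -k * (starts[i] - target) * exp(-k * (t[sel] - protocol$events$time[i]))
    } else {
      0
    }
  }
  out
}

#' Flow-chamber rate constants for a strain preset
#'
#' Exponential rise/fall constants fitted per flow speed are configuration;
#' this reads the shipped calibration (see [chemodyn_config_path()]).
#'
#' @param strain `"WT1"` (fast flow) or `"WT2"` (slower flow, also used for
#'   the CheB mutant).
#' @param path Optional alternative YAML configuration.
#' @return Named list with `k_rise` and `k_fall`, 1/s.
#' @export
default_flow <- function(strain = c("WT1", "WT2", "CHEB_MUTANT"),
                         path = chemodyn_config_path()) {
  strain <- match.arg(strain)
  cfg <- chemodyn_config(path)$flow
  if (strain == "WT1") cfg$wt1 else cfg$wt2
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "<step_protocol> ambient %g mM, %d event(s), k_rise %g /s, k_fall %g /s, t_end %g s\n",
    x$L_ambient, nrow(x$events), x$k_rise, x$k_fall, x$t_end
  ))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}
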