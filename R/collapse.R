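#' Block-average smoothing of a sampled series
#'
#' Averages every `window` subsequent data points into non-overlapping
#' blocks: each numeric column is replaced by its block mean and the block
#' timestamp is the block-mean time. A tail shorter than the window is
#' dropped (not partially averaged), so every smoothed point has the same
#' variance.
#'
#' @param df Data frame with a numeric time column `t` and value columns.
#' @param window Block length in points (`>= 1`; 1 is the identity).
#' @return A tibble of block means.
#' @export
smooth_blocks <- function(df, window = 20) {
  if (window < 1) abort("smoothing window must be at least 1")
  window <- as.integer(window)
  n_blocks <- nrow(df) %/% window
  if (n_blocks == 0) return(tibble::as_tibble(df)[0, ])
  idx <- rep(seq_len(n_blocks), each = window)
  used <- tibble::as_tibble(df)[seq_len(n_blocks * window), ]
  dplyr::summarise(
    dplyr::group_by(dplyr::mutate(used, .block = idx), .data$.block),
    dplyr::across(dplyr::where(is.numeric), mean),
    .groups = "drop"
  )[, names(df)]
}

#' Difference-quotient rate of change
#'
#' Approximates the time derivative of a column by the forward difference
#' quotient \eqn{(x_{i+1} - x_i)/(t_{i+1} - t_i)}. With `pairing = "left"`
#' the quotient is paired with the left-endpoint value `x_i`; with
#' `"midpoint"` it is paired with the mean of the two endpoint values, which
#' removes the leading-order discretisation bias of the pairing.
#'
#' @param df Data frame with columns `t` and `col` (at least 2 rows,
#'   strictly increasing `t`).
#' @param col Name of the column to differentiate.
#' @param pairing `"midpoint"` (default) or `"left"`.
#' @return A tibble with columns `t`, `col` and `d<col>_dt`, one row per
#'   consecutive pair.
#' @export
rate_of_change <- function(df, col = "A", pairing = c("midpoint", "left")) {
  pairing <- match.arg(pairing)
  if (nrow(df) < 2) abort("need at least 2 points for a difference quotient")
  t <- df$t
  if (any(diff(t) <= 0)) abort("time must be strictly increasing")
  x <- df[[col]]
  d <- diff(x) / diff(t)
  paired <- if (pairing == "left") head(x, -1) else (head(x, -1) + tail(x, -1)) / 2
  t_out <- if (pairing == "left") head(t, -1) else (head(t, -1) + tail(t, -1)) / 2
  out <- tibble::tibble(t = t_out, !!col := paired, !!paste0("d", col, "_dt") := d)
  out
}

#' Extract the (activity, rate-of-activity-change) data collapse
#'
#' Converts a simulated or measured activity time course into the condensed
#' collapse representation: for every post-event segment of the protocol the
#' series is block-averaged ([smooth_blocks()]), differentiated by the
#' difference quotient ([rate_of_change()]), and the first `onset_delay`
#' seconds after the step onset are discarded so flow transients do not
#' contaminate the adaptation signal. For precise adaptation at constant
#' ligand all segments fall on the single model curve \eqn{g(A)}.
#'
#' @param tc A `chemo_timecourse` (columns `t`, `A`, `A_norm`; protocol in
#'   attributes).
#' @param onset_delay Seconds discarded after each step onset.
#' @param window Smoothing block length in points.
#' @param pairing Pairing convention for [rate_of_change()].
#' @return A tibble of class `chemo_collapse` with columns `segment`,
#'   `direction`, `delta`, `A`, `dAdt`, `A_norm`, `dAnorm_dt`; complex size,
#'   pre-stimulus activity and model carried as attributes. Segments shorter
#'   than the delay plus two smoothing windows contribute no points (with a
#'   warning).
#' @export
extract_collapse <- function(tc, onset_delay = 10, window = 20,
                             pairing = c("midpoint", "left")) {
  pairing <- match.arg(pairing)
  protocol <- attr(tc, "protocol")
  if (is.null(protocol) || nrow(protocol$events) == 0) {
    abort("the time course carries no protocol events to segment by")
  }
  ev <- protocol$events
  seg_end <- c(ev$time[-1], protocol$t_end)
  pieces <- purrr::map(seq_len(nrow(ev)), function(i) {
    sel <- tc$t >= ev$time[i] + onset_delay & tc$t < seg_end[i]
    seg <- tc[sel, c("t", "A", "A_norm")]
    if (nrow(seg) < 2 * window) {
      warn(sprintf("segment %d shorter than delay + 2 smoothing windows: no collapse points", i))
      return(NULL)
    }
    sm <- smooth_blocks(seg, window)
    ra <- rate_of_change(sm, "A", pairing)
    rn <- rate_of_change(sm[, c("t", "A_norm")], "A_norm", pairing)
    tibble::tibble(
      segment = i, direction = ev$kind[i], delta = ev$delta[i],
      A = ra$A, dAdt = ra$dA_dt, A_norm = rn$A_norm, dAnorm_dt = rn$dA_norm_dt
    )
  })
  out <- dplyr::bind_rows(pieces)
  structure(out,
    class = c("chemo_collapse", class(out)),
    N = attr(tc, "N"), A0 = attr(tc, "A0"),
    spec = attr(tc, "spec"), params = attr(tc, "params"),
    L_ambient = protocol$L_ambient
  )
}

#' Bind collapse sets from several time courses
#'
#' @param ... `chemo_collapse` tibbles sharing one pre-stimulus state.
#' @return A combined `chemo_collapse` tibble (attributes from the first).
#' @export
bind_collapse <- function(...) {
  sets <- list(...)
  out <- dplyr::bind_rows(lapply(sets, function(s) tibble::as_tibble(s)))
  first <- sets[[1]]
  structure(out,
    class = c("chemo_collapse", class(out)),
    N = attr(first, "N"), A0 = attr(first, "A0"),
    spec = attr(first, "spec"), params = attr(first, "params"),
    L_ambient = attr(first, "L_ambient")
  )
}

#' Effective rate of change of the methylation level
#'
#' Divides each rate of activity change by the analytic
#' \eqn{\partial A/\partial m} at that activity (and the segment's complex
#' size). For segments whose activity change is purely from adaptation the
#' result is proportional to `dm/dt`, giving direct access to the methylation
#' kinetics, which are hard to measure biochemically. Points with saturated
#' activity (`A(1-A) < 1e-4`), where the division degenerates, are dropped.
#'
#' @param cs A `chemo_collapse` tibble.
#' @param params Receptor parameters (default: carried by `cs`).
#' @param N Complex size (default: carried by `cs`).
#' @return The collapse tibble with an added `dmdt_eff` column.
#' @export
effective_dm_dt <- function(cs, params = attr(cs, "params"), N = attr(cs, "N")) {
  if (is.null(params) || is.null(N)) abort("receptor parameters and complex size are required")
  keep <- cs$A * (1 - cs$A) >= 1e-4
  out <- dplyr::mutate(cs[keep, ], dmdt_eff = .data$dAdt / dA_dm_at_A(.data$A, N, params))
  structure(out,
    class = class(cs), N = N, A0 = attr(cs, "A0"),
    spec = attr(cs, "spec"), params = params, L_ambient = attr(cs, "L_ambient")
  )
}

#' One-parameter least-squares fit of the methylation rate constant
#'
#' Fits an adaptation model's collapse curve to extracted collapse points
#' with the methylation rate constant `g_R` as the only free parameter; the
#' demethylation constant is tied to it by the steady-state condition at the
#' adapted activity ([solve_gB()]). Because the tied curve is proportional to
#' `g_R`, the least-squares solution is closed-form:
#' \eqn{\hat g_R = \sum b_i y_i / \sum b_i^2} with `b` the unit-rate model
#' curve.
#'
#' @param cs A `chemo_collapse` tibble (at least 3 points).
#' @param model Registry name of the model to fit (see [adaptation_models()]).
#' @param a Adapted activity the demethylation constant is tied to.
#' @param params Receptor parameters (default: carried by `cs`).
#' @param N Complex size (default: carried by `cs`).
#' @param normalized Fit on the normalized scale (`A_norm`, `dAnorm_dt`)
#'   instead of absolute activity.
#' @param K_R,K_B Michaelis constants for the `mm-*` models.
#' @return An object of class `chemo_fit`: fitted `g_R`, tied `g_B`, residual
#'   sum of squares, point count and the fitted curve. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_gR <- function(cs, model = "power-h3", a = 1 / 3,
                   params = attr(cs, "params"), N = attr(cs, "N"),
                   normalized = FALSE, K_R = 0.1, K_B = 0.1) {
  if (nrow(cs) < 3) abort("need at least 3 collapse points to fit")
  if (is.null(params) || is.null(N)) abort("receptor parameters and complex size are required")
  unit <- adaptation_model(model, a = a, g_R = 1, K_R = K_R, K_B = K_B)
  if (normalized) {
    x <- cs$A_norm
    y <- cs$dAnorm_dt
    b <- collapse_rate(pmin(pmax(x * a, 0), 1), unit, params, N = N) / a
  } else {
    x <- cs$A
    y <- cs$dAdt
    b <- collapse_rate(x, unit, params, N = N)
  }
  g_R <- sum(b * y) / sum(b^2)
  rss <- sum((y - g_R * b)^2)
  fitted <- adaptation_model(model, a = a, g_R = g_R, K_R = K_R, K_B = K_B)
  structure(
    list(
      g_R = g_R, g_B = fitted$g_B, rss = rss, n = length(y),
      model = model, a = a, N = N, normalized = normalized,
      spec = fitted, params = params,
      curve = collapse_curve(fitted, params, N = N, normalized = normalized),
      data = cs
    ),
    class = "chemo_fit"
  )
}

#' @export
print.chemo_fit <- function(x, ...) {
  cat(sprintf(
    "<chemo_fit> %s: g_R = %.5g /s (g_B = %.5g /s), RSS = %.4g over %d points%s\n",
    x$model, x$g_R, x$g_B, x$rss, x$n,
    if (x$normalized) " (normalized scale)" else ""
  ))
  invisible(x)
}

#' Recover the complex size from an addition dose-response curve
#'
#' Least-squares fit of the static MWC model's addition responses to a
#' dose-response table at one ambient concentration, with the complex size
#' `N` as the only free parameter. This is how the complex-size-vs-ambient
#' map is calibrated from data.
#'
#' @param dr Tibble with columns `delta` and `response` (addition responses,
#'   normalized), at ambient `L_ambient`.
#' @param L_ambient Ambient concentration, mM.
#' @param params A [receptor_params()] object (its size map is ignored here).
#' @param a Adapted activity.
#' @param interval Search interval for `N`, dimers.
#' @return Fitted complex size (dimers).
#' @export
fit_complex_size <- function(dr, L_ambient, params, a, interval = c(1, 60)) {
  obj <- function(N) {
    m_a <- adapted_methylation(L_ambient, a, params, N)
    pred <- abs(receptor_activity(m_a, L_ambient + dr$delta, params, N) / a - 1)
    sum((pred - dr$response)^2)
  }
  optimize(obj, interval = interval, tol = 1e-8)$minimum
}

# Resolve a model argument for the permutation test into a curve function.
as_collapse_curve <- function(obj, normalized) {
  if (inherits(obj, "chemo_fit")) {
    if (!identical(obj$normalized, normalized)) {
      return(collapse_curve(obj$spec, obj$params, N = obj$N, normalized = normalized))
    }
    return(obj$curve)
  }
  if (is.function(obj)) return(obj)
  abort("model must be a chemo_fit or a function of activity")
}

#' Binned permutation test between two collapse data sets
#'
#' Tests whether two collapse data sets (e.g. two strains) are significantly
#' different under their respective model curves. The activity axis is
#' divided into bins covering the range shared by both sets; each permutation
#' picks `n_pairs` bins and swaps one randomly chosen point between the sets
#' within each, and the squared error is recomputed as the sum over both sets
#' of squared deviations from their own model curves (swapped points are
#' scored against the other set's model). If the sets genuinely follow their
#' own models, the unpermuted error sits below the permuted distribution.
#'
#' With identical sets and identical models every permuted error equals the
#' unpermuted error (swap invariance).
#'
#' @param csA,csB `chemo_collapse` tibbles.
#' @param modelA,modelB `chemo_fit` objects or functions mapping activity to
#'   the predicted rate of activity change (on the scale set by
#'   `normalized`).
#' @param bin_edges Bin boundaries on the activity axis; default: `n_pairs`
#'   equal-width bins over the shared activity range.
#' @param n_pairs Number of pairs swapped per permutation (one per chosen
#'   bin; cannot exceed the number of bins).
#' @param n_permutations Number of permutations (0 allowed: the unpermuted
#'   error is still computed).
#' @param seed Integer seed for the swap RNG.
#' @param normalized Use the normalized columns (`A_norm`, `dAnorm_dt`).
#' @return An object of class `chemo_permtest` with the unpermuted error,
#'   the permuted error distribution, bins and bookkeeping. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
permutation_test <- function(csA, csB, modelA, modelB, bin_edges = NULL,
                             n_pairs = 4, n_permutations = 1000, seed = 1,
                             normalized = TRUE) {
  fA <- as_collapse_curve(modelA, normalized)
  fB <- as_collapse_curve(modelB, normalized)
  xcol <- if (normalized) "A_norm" else "A"
  ycol <- if (normalized) "dAnorm_dt" else "dAdt"
  xA <- csA[[xcol]]; yA <- csA[[ycol]]
  xB <- csB[[xcol]]; yB <- csB[[ycol]]
  if (is.null(bin_edges)) {
    lo <- max(min(xA), min(xB))
    hi <- min(max(xA), max(xB))
    if (!(hi > lo)) abort("the two sets share no activity range to bin")
    bin_edges <- seq(lo, hi, length.out = n_pairs + 1)
  }
  n_bins <- length(bin_edges) - 1
  if (n_pairs > n_bins) abort("n_pairs cannot exceed the number of bins")
  binA <- purrr::map(seq_len(n_bins), function(b) {
    which(xA >= bin_edges[b] & (if (b == n_bins) xA <= bin_edges[b + 1] else xA < bin_edges[b + 1]))
  })
  binB <- purrr::map(seq_len(n_bins), function(b) {
    which(xB >= bin_edges[b] & (if (b == n_bins) xB <= bin_edges[b + 1] else xB < bin_edges[b + 1]))
  })
  empty <- which(lengths(binA) == 0 | lengths(binB) == 0)
  if (length(empty)) {
    abort(sprintf("bin(s) %s contain no point from one of the sets", paste(empty, collapse = ", ")))
  }
  ownA <- (yA - fA(xA))^2; crossA <- (yA - fB(xA))^2
  ownB <- (yB - fB(xB))^2; crossB <- (yB - fA(xB))^2
  unpermuted <- sum(ownA) + sum(ownB)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      bins <- if (n_bins == n_pairs) seq_len(n_bins) else sample.int(n_bins, n_pairs)
      delta <- 0
      for (b in bins) {
        ia <- binA[[b]][sample.int(length(binA[[b]]), 1)]
        ib <- binB[[b]][sample.int(length(binB[[b]]), 1)]
        delta <- delta + (crossA[ia] - ownA[ia]) + (crossB[ib] - ownB[ib])
      }
      unpermuted + delta
    }, numeric(1))
  })
  structure(
    list(
      unpermuted_error = unpermuted, permuted_errors = permuted,
      n_pairs = n_pairs, n_permutations = n_permutations, seed = seed,
      bin_edges = bin_edges, normalized = normalized,
      n_points = c(A = length(xA), B = length(xB))
    ),
    class = "chemo_permtest"
  )
}

#' @export
print.chemo_permtest <- function(x, ...) {
  cat(sprintf(
    "<chemo_permtest> unpermuted error %.5g; %d permutations of %d pairs",
    x$unpermuted_error, x$n_permutations, x$n_pairs
  ))
  if (x$n_permutations > 0) {
    cat(sprintf(
      "; permuted range [%.5g, %.5g], fraction above unpermuted %.3f",
      min(x$permuted_errors), max(x$permuted_errors),
      mean(x$permuted_errors > x$unpermuted_error)
    ))
  }
  cat("\n")
  invisible(x)
}
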