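#' Plot an activity time course
#'
#' Normalized activity and ligand concentration against time.
#'
#' @param object A `chemo_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemo_timecourse
#' @export
autoplot.chemo_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "L", "A_norm")],
    c("A_norm", "L"),
    names_to = "series", values_to = "value"
  )
  labels <- c(A_norm = "normalized activity", L = "MeAsp [mM]")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series,
      ncol = 1, scales = "free_y",
      labeller = ggplot2::as_labeller(labels)
    ) +
    ggplot2::labs(x = "time [s]", y = NULL)
}

#' Plot a data collapse
#'
#' Collapse points (rate of activity change against activity), coloured by
#' stimulus direction, with the adaptation-only model curve overlaid when
#' the collapse set carries its generating model.
#'
#' @param object A `chemo_collapse`.
#' @param normalized Plot the normalized scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemo_collapse
#' @export
autoplot.chemo_collapse <- function(object, normalized = FALSE, ...) {
  x <- if (normalized) "A_norm" else "A"
  y <- if (normalized) "dAnorm_dt" else "dAdt"
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data[[x]], .data[[y]], colour = .data$direction)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = if (normalized) "normalized activity" else "activity A",
      y = if (normalized) "d(A/a)/dt [1/s]" else "dA/dt [1/s]"
    )
  spec <- attr(object, "spec")
  params <- attr(object, "params")
  if (!is.null(spec) && !is.null(params) && !spec$imprecise) {
    f <- collapse_curve(spec, params, N = attr(object, "N"), normalized = normalized)
    lim <- range(object[[x]])
    grid <- tibble::tibble(xv = seq(lim[1], lim[2], length.out = 200))
    grid$yv <- f(grid$xv)
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(.data$xv, .data$yv),
      inherit.aes = FALSE, colour = "grey40", linewidth = 1
    )
  }
  p
}

#' Plot dose-response curves
#'
#' Initial response amplitude against step size (log axis), one panel per
#' ambient concentration, coloured by direction.
#'
#' @param object A `chemo_doseresponse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemo_doseresponse
#' @export
autoplot.chemo_doseresponse <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data$delta, .data$response, colour = .data$direction)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~L_ambient, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "step size [mM]", y = "normalized response amplitude")
}

#' Plot a collapse fit
#'
#' The fitted collapse curve over the points it was fitted to.
#'
#' @param object A `chemo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemo_fit
#' @export
autoplot.chemo_fit <- function(object, ...) {
  x <- if (object$normalized) "A_norm" else "A"
  y <- if (object$normalized) "dAnorm_dt" else "dAdt"
  d <- tibble::as_tibble(object$data)
  lim <- range(d[[x]])
  grid <- tibble::tibble(xv = seq(lim[1], lim[2], length.out = 200))
  grid$yv <- object$curve(grid$xv)
  ggplot2::ggplot(d, ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(.data$xv, .data$yv),
      inherit.aes = FALSE, colour = "red"
    ) +
    ggplot2::labs(
      x = "activity", y = "rate of activity change [1/s]",
      title = sprintf("%s fit: g_R = %.4g /s", object$model, object$g_R)
    )
}

#' Plot a permutation-test distribution
#'
#' Histogram of the permuted squared errors with the unpermuted error marked.
#'
#' @param object A `chemo_permtest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemo_permtest
#' @export
autoplot.chemo_permtest <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$error)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = object$unpermuted_error,
      colour = "red", linewidth = 1
    ) +
    ggplot2::labs(
      x = "squared error", y = "permutations",
      title = sprintf(
        "unpermuted error %.4g (%d permutations, %d pairs)",
        object$unpermuted_error, object$n_permutations, object$n_pairs
      )
    )
}

#' @export
plot.chemo_timecourse <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.chemo_collapse <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.chemo_doseresponse <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.chemo_fit <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.chemo_permtest <- function(x, ...) print(autoplot(x, ...))
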