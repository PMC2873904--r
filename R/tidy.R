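#' Tidy a collapse fit
#'
#' @param x A `chemo_fit` from [fit_gR()].
#' @param ... Unused.
#' @return One row per model constant: the fitted methylation rate `g_R` and
#'   the tied demethylation rate `g_B`.
#' @method tidy chemo_fit
#' @export
tidy.chemo_fit <- function(x, ...) {
  tibble::tibble(
    term = c("g_R", "g_B"),
    estimate = c(x$g_R, x$g_B),
    fitted = c(TRUE, FALSE)
  )
}

#' @rdname tidy.chemo_fit
#' @return `glance()`: a one-row summary with the residual sum of squares,
#'   point count, model name and adapted activity.
#' @method glance chemo_fit
#' @export
glance.chemo_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, a = x$a, g_R = x$g_R, g_B = x$g_B,
    rss = x$rss, n = x$n, normalized = x$normalized
  )
}

#' Tidy a permutation test
#'
#' @param x A `chemo_permtest` from [permutation_test()].
#' @param ... Unused.
#' @return One row per permutation with its squared error.
#' @method tidy chemo_permtest
#' @export
tidy.chemo_permtest <- function(x, ...) {
  tibble::tibble(
    permutation = seq_len(x$n_permutations),
    error = x$permuted_errors
  )
}

#' @rdname tidy.chemo_permtest
#' @return `glance()`: one row with the unpermuted error, the permuted
#'   distribution summary, and the fraction of permutations at or below the
#'   unpermuted error (a permutation p-value).
#' @method glance chemo_permtest
#' @export
glance.chemo_permtest <- function(x, ...) {
  tibble::tibble(
    unpermuted_error = x$unpermuted_error,
    n_permutations = x$n_permutations,
    n_pairs = x$n_pairs,
    min_permuted = if (x$n_permutations) min(x$permuted_errors) else NA_real_,
    median_permuted = if (x$n_permutations) median(x$permuted_errors) else NA_real_,
    p_value = if (x$n_permutations) {
      mean(x$permuted_errors <= x$unpermuted_error)
    } else {
      NA_real_
    }
  )
}
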