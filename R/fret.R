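#' FRET calibration of an experiment
#'
#' Per-experiment calibration of the CFP/YFP intensity-ratio readout: the
#' ratio at a saturating dose of attractant (`R_sat`, zero pathway activity),
#' the adapted pre-stimulus ratio (`R_0`, activity normalized to 1), the
#' fluorescence efficiency ratio `alpha` of the optical setup, and the
#' sampling resolution.
#'
#' @param R_0 Pre-stimulus ratio (both `R_0` and `R_sat` are measured in each
#'   experiment).
#' @param R_sat Ratio at saturating attractant; must differ from `R_0`.
#' @param alpha Fluorescence efficiency ratio (`> 0`); 0.43 in the reference
#'   calibration.
#' @param dt_sample Sampling resolution, s (0.2 for WT1-like, 1 for
#'   WT2/CheB-mutant-like recordings).
#' @return An object of class `fret_calibration`.
#' @export
fret_calibration <- function(R_0 = 1, R_sat = 0.75, alpha = 0.43, dt_sample = 0.2) {
  if (R_sat == R_0) abort("R_sat and R_0 must differ")
  if (alpha <= 0) abort("alpha must be positive")
  if (dt_sample <= 0) abort("dt_sample must be positive")
  structure(list(R_0 = R_0, R_sat = R_sat, alpha = alpha, dt_sample = dt_sample),
    class = "fret_calibration"
  )
}

#' Convert a FRET ratio series to normalized activity
#'
#' Maps the intensity ratio to the number of interacting FRET pairs
#' normalized by its adapted pre-stimulus value, which proxies the normalized
#' pathway activity: `R = R_0` maps to 1, `R = R_sat` maps to 0, strictly
#' monotone in between.
#'
#' Two transforms are available behind a switch:
#' * `"linear"` (default): `(R - R_sat) / (R_0 - R_sat)`.
#' * `"ratiometric"`: `(R - R_sat)(1 + alpha R_0) / ((R_0 - R_sat)(1 + alpha R))`,
#'   which weights the ratio by the fluorescence efficiency `alpha`.
#'
#' Both satisfy the same endpoint contract; the ratiometric form differs only
#' in curvature between the endpoints. Ratios beyond the saturating end
#' (mapping to negative activity) are clamped to `R_sat` with a warning;
#' ratios beyond `R_0` are legitimate — after attractant removal the
#' normalized activity transiently exceeds 1 — and pass through unchanged.
#'
#' @param df Data frame with columns `t` and `R`.
#' @param calib A [fret_calibration()].
#' @param method `"linear"` or `"ratiometric"`.
#' @return A tibble with columns `t` and `A_norm`.
#' @export
ratio_to_activity <- function(df, calib, method = c("linear", "ratiometric")) {
  method <- match.arg(method)
  R <- df$R
  below <- if (calib$R_0 > calib$R_sat) R < calib$R_sat else R > calib$R_sat
  if (any(below)) {
    warn(sprintf("%d ratio value(s) beyond the saturating calibration point; clamped", sum(below)))
    R[below] <- calib$R_sat
  }
  A_norm <- switch(method,
    linear = (R - calib$R_sat) / (calib$R_0 - calib$R_sat),
    ratiometric = (R - calib$R_sat) * (1 + calib$alpha * calib$R_0) /
      ((calib$R_0 - calib$R_sat) * (1 + calib$alpha * R))
  )
  tibble::tibble(t = df$t, A_norm = A_norm)
}

#' Convert normalized activity to a FRET ratio series
#'
#' Exact inverse of [ratio_to_activity()] for each transform; used by the
#' synthetic-data generator to emit ratio series with a known ground truth.
#'
#' @param df Data frame with columns `t` and `A_norm` (non-negative).
#' @param calib A [fret_calibration()].
#' @param method `"linear"` or `"ratiometric"`.
#' @return A tibble with columns `t` and `R`.
#' @export
activity_to_ratio <- function(df, calib, method = c("linear", "ratiometric")) {
  method <- match.arg(method)
  x <- df$A_norm
  if (any(x < 0)) abort("normalized activity must be non-negative")
  R <- switch(method,
    linear = calib$R_sat + x * (calib$R_0 - calib$R_sat),
    ratiometric = {
      d <- x * (calib$R_0 - calib$R_sat) / (1 + calib$alpha * calib$R_0)
      (calib$R_sat + d) / (1 - calib$alpha * d)
    }
  )
  tibble::tibble(t = df$t, R = R)
}

# Shared delimited-text reader: header required, columns resolved by name,
# locale-independent decimal point, malformed rows reported with line numbers.
read_chemo_table <- function(path, required) {
  tab <- tryCatch(
    readr::read_delim(path,
      delim = NULL, comment = "#", show_col_types = FALSE, trim_ws = TRUE,
      locale = readr::locale(decimal_mark = ".")
    ),
    error = function(e) abort(sprintf("cannot read '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(tab) == 0 && ncol(tab) == 0) abort(sprintf("'%s' contains no table", path))
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    abort(sprintf(
      "malformed rows in '%s': %s",
      path, paste(sprintf("line %d (%s)", probs$row, probs$expected), collapse = "; ")
    ))
  }
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(sprintf("'%s' lacks required column(s): %s", path, paste(missing, collapse = ", ")))
  }
  tab[, c(required, setdiff(names(tab), required))]
}

#' Read / write time-course tables
#'
#' Delimited text (comma written; comma, tab or semicolon read) with a header
#' line; columns are resolved by name, so column order in the file does not
#' matter. Floats round-trip loss-free. Optional `# key: value` comment lines
#' carry provenance and are skipped on reading.
#'
#' @param path File path.
#' @param df Table to write (must contain columns `t`, `L`, `m`, `A`,
#'   `A_norm` for a time course).
#' @param meta Optional named character vector written as `# key: value`
#'   header comments.
#' @return `read_timecourse()` returns a tibble; `write_timecourse()` returns
#'   `path` invisibly.
#' @export
read_timecourse <- function(path) {
  read_chemo_table(path, required = c("t", "L", "m", "A", "A_norm"))
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(df, path, meta = NULL) {
  write_chemo_table(df, path, meta)
}

write_chemo_table <- function(df, path, meta = NULL) {
  lines <- character(0)
  if (!is.null(meta)) lines <- sprintf("# %s: %s\n", names(meta), unname(meta))
  writeLines(c(lines, readr::format_csv(tibble::as_tibble(df))), path, sep = "")
  invisible(path)
}

#' Read / write collapse-set tables
#'
#' Same delimited format as [read_timecourse()], with the collapse columns
#' `segment`, `direction`, `delta`, `A`, `dAdt`, `A_norm`, `dAnorm_dt`.
#'
#' @inheritParams read_timecourse
#' @export
read_collapse <- function(path) {
  read_chemo_table(path, required = c("segment", "direction", "delta", "A", "dAdt", "A_norm", "dAnorm_dt"))
}

#' @rdname read_collapse
#' @export
write_collapse <- function(df, path, meta = NULL) {
  write_chemo_table(df, path, meta)
}
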