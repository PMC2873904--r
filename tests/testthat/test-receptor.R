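p <- test_params()

test_that("methylation energy is the configured line and rejects negative m", {
  expect_equal(methylation_energy(0, p), p$fm_intercept)
  for (m in c(0, 1.3, 4, 7.9)) {
    expect_equal(methylation_energy(m + 1, p) - methylation_energy(m, p), p$fm_slope)
  }
  m_grid <- seq(0, 8, by = 0.5)
  expect_true(all(diff(methylation_energy(m_grid, p)) < 0))
  expect_error(methylation_energy(-0.1, p), "non-negative")
})

test_that("a least-squares refit of sampled energies recovers the configured line", {
  # brute-force oracle: refit the line through tabulated (m, f) points
  m_pts <- 0:4
  fit <- stats::lm(f ~ m, data = data.frame(m = m_pts, f = methylation_energy(m_pts, p)))
  expect_equal(unname(coef(fit)), c(p$fm_intercept, p$fm_slope), tolerance = 1e-10)
})

test_that("free energy matches a term-by-term oracle and its limits", {
  # L = 0: every log factor is ln(1) = 0
  expect_equal(free_energy(2.5, 0, p, N = 10), 10 * methylation_energy(2.5, p))
  # L -> infinity: per-dimer ligand term approaches the log-ratio asymptote
  asym <- p$nu_a * log(p$K_on_a / p$K_off_a) + p$nu_s * log(p$K_on_s / p$K_off_s)
  big <- free_energy(2, 1e12, p, N = 1) - methylation_energy(2, p)
  expect_equal(big, asym, tolerance = 1e-4)
  # independent re-derivation, each log factor evaluated separately
  oracle <- function(m, L, N) {
    terms <- c(
      p$nu_a * log1p(L / p$K_off_a), -p$nu_a * log1p(L / p$K_on_a),
      p$nu_s * log1p(L / p$K_off_s), -p$nu_s * log1p(L / p$K_on_s)
    )
    N * (p$fm_intercept + p$fm_slope * m + sum(terms))
  }
  withr::with_seed(11, {
    for (i in 1:50) {
      m <- runif(1, 0, 8); L <- 10^runif(1, -3, 1); N <- runif(1, 5, 30)
      expect_equal(free_energy(m, L, p, N), oracle(m, L, N), tolerance = 1e-12)
    }
  })
})

test_that("activity is the two-state logistic with safe extremes", {
  expect_identical(activity(0), 0.5)
  expect_equal(activity(log(2)), 1 / 3)
  F <- seq(-5, 5, by = 0.25)
  expect_equal(activity(F) + activity(-F), rep(1, length(F)))
  expect_true(all(diff(activity(F)) < 0))
  expect_identical(activity(1e6), activity(700))
  expect_equal(activity(1e6), 0, tolerance = 1e-300)
  expect_equal(activity(-1e6), 1)
  expect_error(activity(NaN), "finite")
})

test_that("complex size map is linear in the ambient concentration", {
  expect_equal(complex_size(0, p), p$size_intercept)
  x <- c(0.1, 0.5, 2)
  expect_equal(complex_size(2 * x, p) - complex_size(x, p), p$size_slope * x)
  expect_error(complex_size(-1, p), "non-negative")
})

test_that("activity is monotone in ligand and methylation on a grid", {
  m_grid <- seq(0.5, 7.5, length.out = 15)
  L_grid <- c(0, 10^seq(-3, 1, length.out = 15))
  for (m in m_grid) {
    expect_true(all(diff(receptor_activity(m, L_grid, p, N = 15)) <= 0))
  }
  for (L in L_grid) {
    expect_true(all(diff(receptor_activity(m_grid, L, p, N = 15)) >= 0))
  }
})

test_that("analytic activity derivatives match finite differences", {
  fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
  withr::with_seed(23, {
    states <- random_responsive_states(200, p)
    for (i in 1:200) {
      m <- states$m[i]; L <- states$L[i]; N <- states$N[i]
      dm_num <- fd(function(m.) receptor_activity(m., L, p, N), m)
      dL_num <- fd(function(L.) receptor_activity(m, L., p, N), L, h = 1e-6 * max(L, 1))
      expect_equal(d_activity_dm(m, L, p, N), dm_num, tolerance = 1e-5)
      expect_equal(d_activity_dL(m, L, p, N), dL_num, tolerance = 1e-5)
      expect_gt(d_activity_dm(m, L, p, N), 0)
      expect_lt(d_activity_dL(m, L, p, N), 0)
    }
  })
})

test_that("dA/dm vanishes at saturation and peaks at half activity", {
  expect_equal(d_activity_dm(0, 50, p, N = 25), 0, tolerance = 1e-8)
  # fixed L and N: the A(1-A) factor is maximal where A = 1/2
  m_half <- adapted_methylation(0.1, 0.5, p, N = 15)
  m_grid <- seq(0.5, 7.5, length.out = 100)
  vals <- d_activity_dm(m_grid, 0.1, p, N = 15)
  expect_lt(max(vals), d_activity_dm(m_half, 0.1, p, N = 15) + 1e-12)
})

test_that("static-model response amplitude saturates for huge steps", {
  a <- 1 / 3
  amps <- vapply(
    c(10, 100, 1e3, 1e4),
    function(d) static_response(0.1, d, "ADD", p, a), numeric(1)
  )
  expect_true(all(diff(amps) >= 0))
  expect_lt(amps[4] - amps[3], 1e-3)
})

test_that("refitting N on a synthetic addition dose-response recovers the truth", {
  a <- 1 / 3
  for (L0 in c(0, 0.5)) {
    N_true <- complex_size(L0, p)
    deltas <- c(0.01, 0.03, 0.1, 0.3, 1, 3)
    m_a <- adapted_methylation(L0, a, p, N_true)
    dr <- tibble::tibble(
      delta = deltas,
      response = abs(receptor_activity(m_a, L0 + deltas, p, N_true) / a - 1)
    )
    N_hat <- fit_complex_size(dr, L0, p, a)
    expect_lt(abs(N_hat - N_true) / N_true, 0.1)
  }
})

test_that("receptor parameter invariants are enforced", {
  expect_error(receptor_params(0.4, 0.6, 0.5, 0.02, 100, 1e6, 1, -0.5, 17.5, 3.35), "K_off")
  expect_error(receptor_params(0.4, 0.7, 0.02, 0.5, 100, 1e6, 1, -0.5, 17.5, 3.35), "equal 1")
  expect_error(receptor_params(0.4, 0.6, 0.02, 0.5, 100, 1e6, 1, 0.5, 17.5, 3.35), "negative")
  expect_error(free_energy(2, 0.1, p, N = 0.5), "at least 1")
})
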