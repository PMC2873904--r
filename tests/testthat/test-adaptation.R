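p <- test_params()

test_that("methylation kinetics balance at the adapted activity by construction", {
  for (name in adaptation_models()) {
    spec <- adaptation_model(name, a = 0.4, g_R = 0.01)
    expect_equal(dm_dt(0.4, m = 1, spec), 0, tolerance = 1e-14)
  }
})

test_that("power-family kinetics have the stated structure", {
  spec <- adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069)
  # inactive complex: pure methylation at rate g_R
  expect_equal(dm_dt(0, spec = spec), spec$g_R)
  # fully active complex: pure demethylation
  expect_equal(dm_dt(1, spec = spec), -spec$g_B)
  # cooperative feedback: demethylation scales as A^3
  A <- c(0.2, 0.5, 0.8)
  expect_equal(
    spec$g_R * (1 - A) - dm_dt(A, spec = spec),
    spec$g_B * A^3
  )
  expect_error(dm_dt(1.2, spec = spec), "\\[0, 1\\]")
  expect_error(dm_dt(-0.1, spec = spec), "\\[0, 1\\]")
})

test_that("solve_gB closed forms match independent root finding", {
  # symmetric balance without feedback
  h1 <- adaptation_model("power-h1", a = 1 / 2, g_R = 0.02)
  expect_equal(h1$g_B, h1$g_R)
  # cooperative feedback at a = 1/3: (1-a)/a^3 = 18
  h3 <- adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069)
  expect_equal(h3$g_B / h3$g_R, 18, tolerance = 1e-12)
  # oracle: numeric root of the balance in g_B for every family
  for (name in adaptation_models()) {
    for (a in c(0.25, 1 / 3, 0.5, 0.7)) {
      spec <- adaptation_model(name, a = a, g_R = 0.0069)
      balance <- function(gB) {
        s2 <- spec; s2$g_B <- gB
        dm_dt(a, m = 1, s2)
      }
      root <- uniroot(balance, c(1e-10, 10), tol = 1e-15)$root
      expect_equal(spec$g_B, root, tolerance = 1e-9)
      expect_lt(abs(dm_dt(a, m = 1, spec)), 1e-12)
    }
  }
  expect_error(solve_gB(0.0069, 1, adaptation_model("power-h3")), "degenerate")
})

test_that("adapted methylation inverts the activity and grows with ambient", {
  # F = 0 at A = 1/2, so m solves f(m) = 0
  expect_equal(
    adapted_methylation(0, 0.5, p),
    -p$fm_intercept / p$fm_slope
  )
  # round trip at arbitrary targets
  for (L in c(0, 0.1, 0.5, 2)) {
    for (a in c(0.2, 1 / 3, 0.5, 0.8)) {
      m <- adapted_methylation(L, a, p)
      expect_equal(receptor_activity(m, L, p), a, tolerance = 1e-10)
    }
  }
  # monotone in ambient, cross-checked against direct bisection
  L_grid <- c(0, 0.05, 0.1, 0.5, 1, 2)
  m_grid <- vapply(L_grid, function(L) adapted_methylation(L, 1 / 3, p), numeric(1))
  expect_true(all(diff(m_grid) > 0))
  for (i in seq_along(L_grid)) {
    N <- complex_size(L_grid[i], p)
    root <- uniroot(
      function(m) receptor_activity(m, L_grid[i], p, N) - 1 / 3,
      c(0, 20), tol = 1e-12
    )$root
    expect_equal(m_grid[i], root, tolerance = 1e-8)
  }
})

test_that("collapse curve vanishes at its fixed points and nowhere else", {
  for (name in c("power-h3", "power-h1", "cheb-mutant", "mm-feedback", "mm-nofeedback")) {
    spec <- adaptation_model(name, a = 1 / 3, g_R = 0.0069)
    g <- function(A) collapse_rate(A, spec, p, L_ambient = 0.1)
    expect_equal(g(0), 0)
    expect_equal(g(1), 0)
    expect_equal(g(spec$a), 0, tolerance = 1e-15)
    # sign pattern on a fine grid: positive below a, negative above
    lo <- seq(1e-3, spec$a - 1e-3, length.out = 300)
    hi <- seq(spec$a + 1e-3, 1 - 1e-3, length.out = 300)
    expect_true(all(g(lo) > 0))
    expect_true(all(g(hi) < 0))
  }
})

test_that("the adapted activity is an attracting fixed point", {
  for (name in c("power-h3", "power-h2", "cheb-mutant")) {
    spec <- adaptation_model(name, a = 1 / 3, g_R = 0.0069)
    h <- 1e-5
    slope <- (collapse_rate(spec$a + h, spec, p, 0.1) -
      collapse_rate(spec$a - h, spec, p, 0.1)) / (2 * h)
    expect_lt(slope, 0)
  }
})

test_that("demethylation side of the collapse is steeper than the methylation side", {
  spec <- adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069)
  a <- spec$a
  expect_gt(
    abs(collapse_rate((1 + a) / 2, spec, p, 0.1)),
    abs(collapse_rate(a / 2, spec, p, 0.1))
  )
})

test_that("saturated Michaelis-Menten kinetics without feedback are flat near the steady state", {
  a <- 1 / 3
  pow <- adaptation_model("power-h3", a = a, g_R = 0.0069)
  mm <- adaptation_model("mm-nofeedback", a = a, g_R = 0.0069)
  near <- c(a - 0.08, a - 0.04, a + 0.04, a + 0.08)
  expect_true(all(
    abs(collapse_rate(near, mm, p, 0.1)) < abs(collapse_rate(near, pow, p, 0.1))
  ))
})

test_that("fixed-point scan finds exactly {0, a, 1} for precise power models", {
  h3 <- adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069)
  expect_equal(fixed_points(h3, p, 0.1), c(0, 1 / 3, 1), tolerance = 1e-8)
  h1 <- adaptation_model("power-h1", a = 1 / 2, g_R = 0.0069)
  expect_equal(fixed_points(h1, p, 0.1), c(0, 1 / 2, 1), tolerance = 1e-8)
  imp <- adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069, imprecise = TRUE)
  expect_error(fixed_points(imp, p, 0.1), "precise")
})

test_that("imprecise site-availability factors scale but never negate the rates", {
  spec <- adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069, imprecise = TRUE)
  m_grid <- seq(0, spec$M_max, length.out = 50)
  # pure methylation (A = 0) stays non-negative, pure demethylation (A = 1) non-positive
  expect_true(all(dm_dt(0, m_grid, spec) >= 0))
  expect_true(all(dm_dt(1, m_grid, spec) <= 0))
  # saturated sites shut the matching process down entirely
  expect_equal(dm_dt(0, spec$M_max, spec), 0)
  expect_equal(dm_dt(1, 0, spec), 0)
  # within one site-scale of the bounds the rates are strictly reduced
  prec <- adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069)
  expect_lt(dm_dt(0, spec$M_max - 0.2, spec), dm_dt(0, spec = prec))
  expect_gt(dm_dt(1, 0.2, spec), dm_dt(1, spec = prec))
  expect_error(dm_dt(0.5, m = NULL, spec), "methylation level")
})

test_that("model registry rejects unknown names with the registry listed", {
  expect_error(adaptation_model("power-h4"), "registry")
  expect_error(adaptation_model("power-h3", a = 0), "\\(0, 1\\)")
  expect_error(
    adaptation_model("power-h3", imprecise = TRUE, m_c = 5, M_max = 4),
    "m_c"
  )
})
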