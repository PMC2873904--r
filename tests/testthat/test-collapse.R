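p <- test_params()

test_that("block smoothing averages non-overlapping windows and drops the tail", {
  const <- tibble::tibble(t = 1:40, A = rep(0.3, 40))
  expect_equal(smooth_blocks(const, 20)$A, c(0.3, 0.3))
  # window 1 is the identity
  df <- tibble::tibble(t = 1:5, A = c(0.1, 0.4, 0.2, 0.9, 0.5))
  expect_equal(smooth_blocks(df, 1), df)
  # linear ramp: block means equal the midpoint values of each block
  ramp <- tibble::tibble(t = 1:60, A = 2 * (1:60))
  sm <- smooth_blocks(ramp, 20)
  expect_equal(sm$t, c(10.5, 30.5, 50.5))
  expect_equal(sm$A, 2 * c(10.5, 30.5, 50.5))
  # 7 trailing points beyond the last full block are dropped
  expect_equal(nrow(smooth_blocks(ramp[1:47, ], 20)), 2)
  expect_error(smooth_blocks(ramp, 0), "at least 1")
})

test_that("difference quotients recover constant and linear rates exactly", {
  t <- seq(0, 10, by = 0.5)
  flat <- tibble::tibble(t = t, A = rep(0.2, length(t)))
  expect_equal(rate_of_change(flat, "A")$dA_dt, rep(0, length(t) - 1))
  lin <- tibble::tibble(t = t, A = 0.03 * t)
  for (pairing in c("left", "midpoint")) {
    rc <- rate_of_change(lin, "A", pairing = pairing)
    expect_equal(rc$dA_dt, rep(0.03, length(t) - 1))
  }
  # left pairing keeps the left endpoint, midpoint averages the two
  rc_l <- rate_of_change(lin, "A", pairing = "left")
  expect_equal(rc_l$A, head(lin$A, -1))
  rc_m <- rate_of_change(lin, "A", pairing = "midpoint")
  expect_equal(rc_m$A, (head(lin$A, -1) + tail(lin$A, -1)) / 2)
  expect_error(rate_of_change(lin[1, ], "A"), "at least 2")
  expect_error(rate_of_change(tibble::tibble(t = c(1, 1, 2), A = 1:3), "A"), "increasing")
})

test_that("noiseless precise time courses collapse onto the model curve", {
  spec <- wt1_model()
  css <- lapply(wt1_campaign_truths(), extract_collapse)
  cs <- do.call(bind_collapse, css)
  g <- collapse_curve(spec, p, N = attr(cs, "N"))
  away <- abs(cs$A - spec$a) > 0.01 # relative error degenerates at the zero of g
  rel <- abs(cs$dAdt[away] - g(cs$A[away])) / abs(g(cs$A[away]))
  # methylation branch (additions): within the 2% collapse tolerance
  expect_lt(max(rel[cs$direction[away] == "ADD"]), 0.02)
  # demethylation branch: fast decay, bounded by the O(dt) quotient bias
  expect_lt(max(rel[cs$direction[away] == "REMOVE"]), 0.06)
  # the smoothed quotient approximates g(A) at O(dt): halving the block length
  # roughly halves the worst methylation-branch deviation ceiling
  cs10 <- extract_collapse(wt1_campaign_truths()[[5]], window = 10)
  away10 <- abs(cs10$A - spec$a) > 0.01 & cs10$direction == "ADD"
  rel10 <- abs(cs10$dAdt[away10] - g(cs10$A[away10])) / abs(g(cs10$A[away10]))
  expect_lt(max(rel10), 0.02)
})

test_that("imprecise adaptation pulls methylation-branch points below the precise curve", {
  spec_imp <- wt1_model(imprecise = TRUE)
  pr <- step_protocol(0.1, tibble::tibble(time = 20, kind = "ADD", delta = 2), t_end = 620)
  tc <- simulate_timecourse(pr, p, spec_imp, dt = 0.2)
  cs <- extract_collapse(tc)
  g_precise <- collapse_curve(wt1_model(), p, N = attr(cs, "N"))
  meth <- cs$dAdt > 0 & cs$A > 0.01
  expect_true(all(cs$dAdt[meth] < g_precise(cs$A[meth])))
})

test_that("short post-event segments yield no collapse points but a warning", {
  pr <- step_protocol(0.1, tibble::tibble(time = 5, kind = "ADD", delta = 0.1), t_end = 20)
  tc <- simulate_timecourse(pr, p, wt1_model(), dt = 0.2)
  expect_warning(cs <- extract_collapse(tc), "no collapse points")
  expect_equal(nrow(cs), 0)
})

test_that("effective methylation rate matches the kinetics and crosses zero at a", {
  spec <- wt1_model()
  cs <- extract_collapse(wt1_campaign_truths()[[2]])
  eff <- effective_dm_dt(cs)
  truth <- dm_dt(eff$A, spec = spec)
  away <- abs(eff$A - spec$a) > 0.01 & eff$direction == "ADD"
  expect_lt(max(abs(eff$dmdt_eff[away] - truth[away]) / abs(truth[away])), 0.02)
  # monotone decreasing in A for the precise power family
  ord <- order(eff$A)
  fit <- stats::lm(eff$dmdt_eff[ord] ~ eff$A[ord])
  expect_lt(coef(fit)[2], 0)
  # sign change brackets the adapted activity
  expect_gt(max(eff$dmdt_eff), 0)
  expect_lt(min(eff$dmdt_eff), 0)
})

test_that("points sampled exactly from the model curve are fitted with zero residual", {
  spec <- wt1_model()
  A <- seq(0.05, 0.95, length.out = 40)
  g <- collapse_curve(spec, p, L_ambient = 0.1)
  cs <- tibble::tibble(
    segment = 1L, direction = "ADD", delta = 0.1,
    A = A, dAdt = g(A), A_norm = A / spec$a, dAnorm_dt = g(A) / spec$a
  )
  f <- fit_gR(cs, "power-h3", a = spec$a, params = p, N = complex_size(0.1, p))
  expect_equal(f$g_R, spec$g_R, tolerance = 1e-10)
  expect_lt(f$rss, 1e-20)
  # the same points described on the normalized scale give the same constant
  fn <- fit_gR(cs, "power-h3",
    a = spec$a, params = p, N = complex_size(0.1, p),
    normalized = TRUE
  )
  expect_equal(fn$g_R, spec$g_R, tolerance = 1e-10)
  expect_error(fit_gR(cs[1:2, ], params = p, N = 17.5), "at least 3")
})

test_that("the generating model outranks the flat Michaelis alternative", {
  cs <- wt1_noisy_campaign_collapse(seed = 42)
  f_true <- fit_gR(cs, "power-h3", a = 1 / 3)
  f_mm <- fit_gR(cs, "mm-nofeedback", a = 1 / 3)
  expect_lt(f_true$rss, f_mm$rss)
  expect_lt(abs(f_true$g_R - 0.0069) / 0.0069, 0.15)
})

test_that("tidy and glance summarise fits", {
  cs <- extract_collapse(wt1_campaign_truths()[[1]])
  f <- fit_gR(cs, "power-h3", a = 1 / 3)
  td <- tidy(f)
  expect_equal(td$term, c("g_R", "g_B"))
  expect_equal(td$estimate[2], solve_gB(td$estimate[1], 1 / 3, f$spec))
  gl <- glance(f)
  expect_equal(gl$n, nrow(cs))
  expect_equal(gl$model, "power-h3")
})

test_that("swapping between identical sets leaves the permutation error unchanged", {
  cs <- extract_collapse(wt1_campaign_truths()[[3]])
  curve <- collapse_curve(wt1_model(), p, N = attr(cs, "N"), normalized = TRUE)
  pt <- permutation_test(cs, cs, curve, curve, n_permutations = 50, seed = 9)
  expect_equal(pt$permuted_errors, rep(pt$unpermuted_error, 50))
  expect_equal(glance(pt)$p_value, 1)
})

test_that("permutation test validates bins and supports zero permutations", {
  cs <- extract_collapse(wt1_campaign_truths()[[3]])
  curve <- collapse_curve(wt1_model(), p, N = attr(cs, "N"), normalized = TRUE)
  pt0 <- permutation_test(cs, cs, curve, curve, n_permutations = 0)
  expect_length(pt0$permuted_errors, 0)
  expect_gt(pt0$unpermuted_error, 0) # noiseless but discretised: small positive
  expect_error(
    permutation_test(cs, cs, curve, curve, n_pairs = 10, bin_edges = c(0.5, 1, 1.5)),
    "cannot exceed"
  )
  expect_error(
    permutation_test(cs, cs, curve, curve, bin_edges = c(100, 101, 102, 103, 104)),
    "no point"
  )
})

test_that("permutation RNG is reproducible by seed", {
  csA <- extract_collapse(wt1_campaign_truths()[[3]])
  csB <- noisy_collapse(wt1_campaign()[[3]], wt1_campaign_truths()[[3]], 1 / 3, seed = 5)
  curveA <- collapse_curve(wt1_model(), p, N = attr(csA, "N"), normalized = TRUE)
  curveB <- collapse_curve(wt2_model(), p, N = attr(csA, "N"), normalized = TRUE)
  p1 <- permutation_test(csA, csB, curveA, curveB, n_permutations = 30, seed = 4)
  p2 <- permutation_test(csA, csB, curveA, curveB, n_permutations = 30, seed = 4)
  p3 <- permutation_test(csA, csB, curveA, curveB, n_permutations = 30, seed = 5)
  expect_identical(p1$permuted_errors, p2$permuted_errors)
  expect_false(identical(p1$permuted_errors, p3$permuted_errors))
})
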