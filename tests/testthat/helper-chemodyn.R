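# Shared fixtures. Expensive ground-truth simulations are cached for the
# duration of one test run; everything is built in code, nothing is stored.

chemo_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = chemo_test_cache)) {
    assign(key, force(expr), envir = chemo_test_cache)
  }
  get(key, envir = chemo_test_cache)
}

test_params <- function() cached("params", default_receptor_params())

wt1_model <- function(...) adaptation_model("power-h3", a = 1 / 3, g_R = 0.0069, ...)
wt2_model <- function() adaptation_model("power-h3", a = 1 / 2, g_R = 0.0069)

# Perfect-step add/adapt/remove campaign at 0.1 mM ambient with the
# reference step sizes, plus its noiseless WT1 ground truths at 0.2 s.
wt1_campaign <- function() cached("wt1_campaign", campaign_protocols())

wt1_campaign_truths <- function() {
  cached("wt1_truths", {
    lapply(wt1_campaign(), function(pr) {
      simulate_timecourse(pr, test_params(), wt1_model(), dt = 0.2)
    })
  })
}

# WT2-like reference recording: 0.5 mM added and removed at zero ambient,
# 1 s sampling, slower flow.
wt2_protocol <- function() {
  step_protocol(0,
    tibble::tibble(time = c(20, 520), kind = c("ADD", "REMOVE"), delta = 0.5),
    k_rise = 0.35, k_fall = 0.45, t_end = 800
  )
}

wt2_truth <- function() {
  cached("wt2_truth", simulate_timecourse(wt2_protocol(), test_params(), wt2_model(), dt = 1))
}

# Random receptor states away from activity saturation: derivatives (and
# their finite-difference oracles) are informative only where A(1-A) is not
# vanishingly small, so states are drawn until the activity is mid-range.
random_responsive_states <- function(n, params) {
  m <- L <- N <- numeric(0)
  while (length(m) < n) {
    mi <- runif(4 * n, 0.5, 7)
    Li <- 10^runif(4 * n, -3, 0.7)
    Ni <- runif(4 * n, 5, 30)
    A <- receptor_activity(mi, Li, params, Ni)
    ok <- A > 0.02 & A < 0.98
    m <- c(m, mi[ok]); L <- c(L, Li[ok]); N <- c(N, Ni[ok])
  }
  tibble::tibble(m = m[1:n], L = L[1:n], N = N[1:n])
}

# Noisy collapse set for one strain-like experiment reusing a cached truth.
noisy_collapse <- function(protocol, truth, a, seed, noise_sd = 0.05,
                           strain = "WT1") {
  sx <- synthetic_experiment(strain, protocol,
    noise_sd = noise_sd, seed = seed, keep_flow = TRUE
  )
  gen <- generate_fret_experiment(sx, test_params(), truth = truth)
  collapse_from_activity(
    ratio_to_activity(gen$ratio, gen$calib), protocol, a, test_params()
  )
}

# Full noisy WT1 campaign collapse set for one seed.
wt1_noisy_campaign_collapse <- function(seed, noise_sd = 0.05) {
  prots <- wt1_campaign()
  truths <- wt1_campaign_truths()
  sets <- lapply(seq_along(prots), function(i) {
    noisy_collapse(prots[[i]], truths[[i]], 1 / 3, seed = seed * 131L + i, noise_sd = noise_sd)
  })
  do.call(bind_collapse, sets)
}
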