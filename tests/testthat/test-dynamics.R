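test_that("leaky unit follows the closed-form exponential relaxation", {
  p <- list(tau = 0.1, sigma = 1, theta = 0)
  # one forward-Euler step from u = 0 with I = 1, dt = 0.05 lands at 0.5
  s <- step_leaky(list(u = 0, v = 0), p, input = 1, dt = 0.05)
  expect_equal(s$u, 0.5)
  # as dt -> 0 the trajectory converges to u(t) = I (1 - exp(-t / tau))
  for (dt in c(1e-3, 1e-4)) {
    s <- list(u = 0, v = 0)
    n <- round(0.2 / dt)
    for (k in seq_len(n)) s <- step_leaky(s, p, input = 1, dt = dt)
    expect_equal(s$u, 1 - exp(-0.2 / 0.1), tolerance = 20 * dt)
  }
})

test_that("leaky unit fixed points: zero input and constant input", {
  p <- list(tau = 0.1, sigma = 2, theta = 0.1)
  s <- list(u = 0, v = 0)
  for (k in 1:100) s <- step_leaky(s, p, input = 0, dt = 0.01)
  expect_equal(s$u, 0)
  expect_equal(s$v, 0)
  # constant input held for 10 tau: u converges to I within 1%
  I <- 0.8
  s <- list(u = 0, v = 0)
  for (k in 1:100) s <- step_leaky(s, p, input = I, dt = 0.01) # t = 1 s = 10 tau
  expect_equal(s$u, I, tolerance = 0.01)
  expect_equal(s$v, max(tanh(p$sigma * (s$u - p$theta)), 0))
})

test_that("non-finite input aborts with a diagnostic", {
  p <- list(tau = 0.1, sigma = 1, theta = 0)
  expect_error(step_leaky(list(u = 0, v = 0), p, input = NaN, dt = 0.05),
               "non-finite")
  expect_error(step_leaky(list(u = 0, v = 0), p, input = 1, dt = 0), "dt")
})

test_that("striatal unit reduces to the leaky unit and scales input with dopamine", {
  lp <- list(tau = 0.1, sigma = 2, theta = 0.1)
  sp <- c(lp, list(iota = 1, delta = 1))
  s1 <- list(u = 0.2, v = 0); s2 <- s1
  for (k in 1:50) {
    s1 <- step_leaky(s1, lp, input = 0.7, dt = 0.05)
    s2 <- step_striatal(s2, sp, input = 0.7, da = 0, dt = 0.05)
  }
  expect_identical(s1, s2) # da = 0, iota = 1: bit-identical trajectories
  # delta = 0 removes any dopamine effect
  sp0 <- c(lp, list(iota = 1, delta = 0))
  s3 <- list(u = 0.2, v = 0)
  for (k in 1:50) s3 <- step_striatal(s3, sp0, input = 0.7, da = 5, dt = 0.05)
  expect_identical(s3, s1)
  # iota = delta = 1, da = 1, I = 0.5: trajectory matches leaky unit with I = 1
  s4 <- list(u = 0, v = 0); s5 <- list(u = 0, v = 0)
  for (k in 1:50) {
    s4 <- step_striatal(s4, sp, input = 0.5, da = 1, dt = 0.01)
    s5 <- step_leaky(s5, lp, input = 1, dt = 0.01)
  }
  expect_equal(s4$u, s5$u, tolerance = 1e-12)
})

test_that("onset unit produces a transient and returns to zero under sustained input", {
  p <- list(tau_o = 0.05, tau_i = 0.5)
  # zero fixed point
  s <- list(u_o = 0, u_i = 0, o = 0)
  for (k in 1:100) s <- step_onset(s, p, input = 0, dt = 0.01)
  expect_equal(s$o, 0)
  # sustained input: u_i -> I so the output decays back toward zero
  s <- list(u_o = 0, u_i = 0, o = 0)
  peak <- 0
  for (k in 1:1000) { # 10 s at dt 0.01
    s <- step_onset(s, p, input = 1, dt = 0.01)
    peak <- max(peak, s$o)
  }
  expect_gt(peak, 0.3)
  expect_lt(s$o, 0.02)
  expect_equal(s$u_i, 1, tolerance = 0.01)
  # peak value and time against the fine-step reference integration
  ref <- onset_reference(function(t) 1, 0.05, 0.5, t_end = 2)
  s <- list(u_o = 0, u_i = 0, o = 0)
  tr <- numeric(200)
  for (k in 1:200) { s <- step_onset(s, p, input = 1, dt = 0.01); tr[k] <- s$o }
  expect_lt(abs(max(tr) - max(ref$o)), 0.03)
  expect_lt(abs(which.max(tr) * 0.01 - ref$t[which.max(ref$o)]), 0.05)
})

test_that("thalamic noise has the AR(1) mean and variance", {
  p <- list(tau_n = 0.5, nu = 2.5)
  dt <- 0.05
  # nu = 0: pure exponential decay
  s <- list(n = 1, z = 0)
  for (k in 1:200) s <- step_noise(s, list(tau_n = 0.5, nu = 0), dt, z = 0)
  expect_lt(abs(s$n), 1e-8)
  # long-run moments vs the discrete AR(1) closed form
  set.seed(42)
  a <- 1 - dt / p$tau_n
  b <- dt / p$tau_n * p$nu
  n_steps <- 2e5
  vals <- numeric(n_steps)
  s <- list(n = 0, z = 0)
  for (k in seq_len(n_steps)) { s <- step_noise(s, p, dt); vals[k] <- s$n }
  var_theory <- b^2 * (1 / 12) / (1 - a^2)
  se_mean <- sqrt(var_theory / n_steps) *
    sqrt((1 + a) / (1 - a))            # effective n corrected for autocorrelation
  expect_lt(abs(mean(vals)), 3 * se_mean)
  expect_equal(var(vals), var_theory, tolerance = 0.05)
  expect_true(all(abs(vals) <= 0.5 * p$nu / (1 - a) + 1)) # sanity bound
})

test_that("all model activations stay in [0, 1) at every step", {
  m <- build_model(default_config(), seed = 5)
  for (i in 1:400) {
    o <- step_model(m, c(lever1 = 1, food1 = as.numeric(i %in% 100:120)),
                    learning_on = TRUE)
    acts <- c(o$bla, o$vta, o$da_dms, o$da_dls,
              unlist(o$goal[c("str", "stn", "gpi", "th", "ctx")]),
              unlist(o$motor[c("str", "stn", "gpi", "th", "ctx")]))
    expect_true(all(acts >= 0 & acts < 1))
  }
})

test_that("halving the integration step barely changes a noiseless trajectory", {
  cfg <- default_config()
  cfg$model$goal$nu <- 0; cfg$model$assoc$nu <- 0; cfg$model$motor$nu <- 0
  m1 <- build_model(cfg, seed = 5)
  cfg2 <- cfg; cfg2$experiment$substeps <- 2
  m2 <- build_model(cfg2, seed = 5)
  worst <- 0
  for (i in 1:400) {
    stim <- c(lever1 = 1, food1 = as.numeric(i %in% 100:120))
    o1 <- step_model(m1, stim)
    o2 <- step_model(m2, stim)
    worst <- max(worst, abs(o1$mc - o2$mc), abs(o1$vta - o2$vta),
                 abs(o1$da_dls - o2$da_dls))
  }
  # documented discretization tolerance at the shipped 0.05 s cycle: the
  # fastest onset units (tau_o = 0.05 s) are integrated at h = tau, so their
  # phasic transients shift by up to ~0.25 when the step is refined; slow
  # (tonic, trace, weight) variables move far less and the behavioral
  # statistics are unaffected (see the methods vignette)
  expect_lt(worst, 0.3)
})
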