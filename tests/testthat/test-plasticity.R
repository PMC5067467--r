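test_that("activity trace relaxes to alpha * o and signals rise and fall", {
  p <- list(alpha = 1, tau_t = 4)
  s <- list(t = 0, t_dot = 0)
  for (k in 1:100) s <- step_trace(s, p, o = 0, dt = 0.05)
  expect_equal(s$t, 0)
  expect_equal(s$t_dot, 0)
  # constant o: converges to alpha * o
  s <- list(t = 0, t_dot = 0)
  for (k in 1:1600) s <- step_trace(s, p, o = 0.5, dt = 0.05) # 80 s = 20 tau_t
  expect_equal(s$t, 0.5, tolerance = 1e-3)
  # pulse: rising during the pulse, falling after; crossover where o drops
  s <- list(t = 0, t_dot = 0)
  signs <- numeric(80)
  for (k in 1:80) {
    s <- step_trace(s, p, o = as.numeric(k <= 40) * 0.8, dt = 0.05)
    signs[k] <- sign(s$t_dot)
  }
  expect_true(all(signs[1:40] == 1))
  expect_true(all(signs[41:80] == -1))
})

test_that("amygdala rule learns only forward sequences under a dopamine burst", {
  p <- list(eta_b = 1, theta_da_bla = 0, max_w_bla = 1)
  pre_fall <- list(t = 1, t_dot = -0.3)
  post_rise <- list(t = 0.5, t_dot = 0.2)
  # worked example: 1 * 0.5 * 0.2 * 0.3 * (1 - 0) = 0.03
  expect_equal(bla_weight_update(0, pre_fall, post_rise, da = 0.5, p), 0.03)
  # gate closed at or below the dopamine threshold
  p2 <- list(eta_b = 1, theta_da_bla = 0.4, max_w_bla = 1)
  expect_equal(bla_weight_update(0, pre_fall, post_rise, da = 0.4, p2), 0)
  # both traces rising: the pre-synaptic factor is zero
  pre_rise <- list(t = 0.2, t_dot = 0.1)
  expect_equal(bla_weight_update(0, pre_rise, post_rise, da = 0.5, p), 0)
  # soft bound: at the ceiling the increment vanishes
  expect_equal(bla_weight_update(1, pre_fall, post_rise, da = 0.5, p), 0)
  # increments are never negative
  for (k in 1:50) {
    set.seed(k)
    dw <- bla_weight_update(runif(1), list(t = 1, t_dot = runif(1, -1, 1)),
                            list(t = 1, t_dot = runif(1, -1, 1)),
                            da = runif(1), p)
    expect_gte(dw, 0)
  }
})

test_that("striatal rule needs a phasic burst and supra-threshold activity", {
  p <- list(eta_str = 0.1, theta_da_str = 0, theta_str = 0, theta_inp_str = 0)
  # worked example: 0.1 * 1 * 0.5 * 0.8 = 0.04
  expect_equal(striatal_weight_update(0, v_inp = 0.8, v_str = 0.5, da = 1, p), 0.04)
  p2 <- list(eta_str = 0.1, theta_da_str = 0.8, theta_str = 0.5, theta_inp_str = 0.5)
  expect_equal(striatal_weight_update(0, 0.9, 0.9, da = 0.7, p2), 0)  # gate closed
  expect_equal(striatal_weight_update(0, 0.9, 0.4, da = 0.95, p2), 0) # losing channel
})

test_that("plastic projections clip to bounds and frozen projections refuse updates", {
  proj <- plastic_projection(matrix(0, 2, 2), "striatal", list(w_cap = 0.5))
  p2 <- apply_updates(proj, matrix(0, 2, 2))
  expect_identical(p2$w, proj$w)
  p3 <- apply_updates(proj, matrix(10, 2, 2))
  expect_true(all(p3$w == 0.5)) # lands exactly on the ceiling
  frozen <- plastic_projection(matrix(1, 2, 2), "striatal", list(w_cap = 2),
                               frozen = TRUE)
  expect_error(apply_updates(frozen, matrix(1, 2, 2)), "frozen")
  expect_error(apply_updates(proj, matrix(0, 3, 3)), "shape")
  # monotone non-decreasing under random non-negative increment sequences
  set.seed(7)
  w_prev <- proj$w
  for (k in 1:30) {
    proj <- apply_updates(proj, matrix(runif(4, 0, 0.05), 2, 2))
    expect_true(all(proj$w >= w_prev))
    w_prev <- proj$w
  }
})

test_that("with dopamine at baseline no plastic weight moves in a full session", {
  m <- build_model(default_config(), seed = 3)
  w0 <- model_weights(m)
  for (i in 1:600) step_model(m, c(lever1 = 1, lever2 = 0), learning_on = TRUE)
  w1 <- model_weights(m)
  expect_identical(w0, w1) # no food, no phasic burst, every gate closed
})

test_that("the CS->US weight grows and the US->CS weight does not", {
  # scripted conditioning: lever 1 on, food 1 delivered a little later
  m <- build_model(default_config(), seed = 4)
  for (rep in 1:10) {
    for (i in 1:120) {
      # food arrives once the cue trace is already decaying (a CS-US sequence)
      food <- as.numeric(i > 80 & i <= 100)
      step_model(m, c(lever1 = 1, food1 = food), learning_on = TRUE)
    }
    reset_model(m)
  }
  w <- model_weights(m)$bla
  expect_gt(w[3, 1], 0.05)    # US1 <- CS1: forward association forms
  expect_equal(w[1, 3], 0)    # CS1 <- US1: no backward association
  expect_equal(w[4, 2], 0)    # untouched units stay silent
  expect_true(all(w <= default_config()$model$bla$max_w))
  expect_true(all(diag(w) == 0)) # no autapses in the lateral bank
})
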