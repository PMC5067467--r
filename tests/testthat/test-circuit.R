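test_that("the built model is reproducible and validates its configuration", {
  cfg <- default_config()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  s1 <- lapply(1:50, function(i) step_model(m1, c(lever1 = 1)))
  m2 <- build_model(cfg, seed = 11) # rebuild to restart the RNG stream
  s2 <- lapply(1:50, function(i) step_model(m2, c(lever1 = 1)))
  expect_identical(s1, s2)
  # a missing parameter is a configuration error naming the parameter
  bad <- cfg; bad$model$vta$tau <- NULL
  expect_error(build_model(bad, 1), "vta.tau")
  bad2 <- cfg; bad2$model$goal$tau_str <- -1
  expect_error(build_model(bad2, 1), "tau_str")
})

test_that("at rest the pallidum is tonically active and the thalamus suppressed", {
  cfg <- default_config()
  cfg$model$goal$nu <- 0; cfg$model$assoc$nu <- 0; cfg$model$motor$nu <- 0
  m <- build_model(cfg, 1)
  o <- NULL
  for (i in 1:200) o <- step_model(m, numeric(0))
  for (loop in list(o$goal, o$assoc, o$motor)) {
    expect_true(all(loop$gpi > 0.2))
    expect_true(all(loop$th == 0))
    expect_true(all(loop$ctx == 0))
  }
  expect_true(all(o$mc < default_config()$experiment$theta_mc))
})

test_that("without noise the circuit is exactly label-exchange symmetric", {
  cfg <- default_config()
  cfg$model$goal$nu <- 0; cfg$model$assoc$nu <- 0; cfg$model$motor$nu <- 0
  m1 <- build_model(cfg, 2); m2 <- build_model(cfg, 2)
  for (i in 1:300) {
    food <- as.numeric(i %in% 150:170)
    o1 <- step_model(m1, c(lever1 = 1, food1 = food, sat1 = 0), learning_on = TRUE)
    o2 <- step_model(m2, c(lever2 = 1, food2 = food, sat2 = 0), learning_on = TRUE)
    expect_equal(o1$bla[c(1, 3)], o2$bla[c(2, 4)], tolerance = 1e-12)
    expect_equal(o1$mc, rev(o2$mc), tolerance = 1e-12)
    expect_equal(o1$da_dms, rev(o2$da_dms), tolerance = 1e-12)
  }
  w1 <- model_weights(m1); w2 <- model_weights(m2)
  perm <- c(2, 1, 4, 3)
  expect_equal(w1$bla, w2$bla[perm, perm], tolerance = 1e-12)
  expect_equal(w1$dls, w2$dls[2:1, 2:1], tolerance = 1e-12)
})

test_that("a food pulse drives phasic onset responses and dopamine bursts", {
  m <- build_model(default_config(), 1)
  for (i in 1:40) o <- step_model(m, numeric(0)) # settle to rest
  baseline <- o$da_dls[1]
  vta <- ppn <- da <- numeric(140)
  for (i in 1:140) {
    o <- step_model(m, c(food1 = as.numeric(i <= 20)))
    vta[i] <- o$vta; ppn[i] <- o$ppn; da[i] <- o$da_dls[1]
  }
  expect_gt(max(ppn), 0.4)      # transient onset response
  expect_gt(max(vta), 0.7)      # phasic burst at the VTA
  expect_gt(max(da), 0.9)       # and at the SNpc dopamine units
  # phasic component returns to within 5% of baseline after the pulse
  expect_lt(vta[140], 0.05)
  expect_lt(abs(da[140] - baseline), 0.05)
})

test_that("tonic dopamine follows sustained striatal drive through the spirals", {
  cfg <- default_config()
  cfg$model$goal$nu <- 0; cfg$model$assoc$nu <- 0; cfg$model$motor$nu <- 0
  m <- build_model(cfg, 1)
  w <- model_weights(m)
  w$dms[1, ] <- 0.5 # sustained lever drive onto the channel-1 DMS unit
  restore_weights(m, w)
  for (i in 1:40) o <- step_model(m, numeric(0))
  da0 <- o$da_dls
  for (i in 1:100) o <- step_model(m, c(lever1 = 1))
  expect_gt(o$da_dls[1], da0[1] + 0.2) # channel-specific tonic increase
  expect_lt(abs(o$da_dls[2] - da0[2]), 0.1)
  # the shift persists for as long as the striatal drive persists
  for (i in 1:100) o <- step_model(m, c(lever1 = 1))
  expect_gt(o$da_dls[1], da0[1] + 0.2)
})

test_that("satiation strictly reduces cue-driven outcome recall at every cycle", {
  cfg <- default_config()
  build_recall <- function(sat2) {
    m <- build_model(cfg, 6)
    w <- model_weights(m); w$bla[4, 2] <- 1.5
    restore_weights(m, w)
    sapply(1:100, function(i)
      step_model(m, c(lever2 = 1, sat2 = sat2))$bla[4])
  }
  us_free <- build_recall(0)
  us_sat <- build_recall(1)
  expect_gt(max(us_free), 0.3)
  expect_true(all(us_sat <= us_free))
  expect_true(all(us_sat == 0)) # default inhibition fully suppresses recall
})

test_that("lesion clamps are absorbing and exact", {
  m <- build_model(default_config(), 1)
  apply_lesion(m, "bla")
  for (i in 1:50) {
    o <- step_model(m, c(lever1 = 1, food1 = 1))
    expect_identical(o$bla, rep(0, 4))
  }
  m2 <- build_model(default_config(), 1)
  apply_lesion(m2, lesion_spec("pl", "post"))
  for (i in 1:50) expect_identical(step_model(m2, c(lever1 = 1))$goal$ctx, c(0, 0))
  expect_error(apply_lesion(m2, "cerebellum"))
})

test_that("spiral disconnection freezes tonic dopamine at baseline", {
  cfg <- default_config()
  cfg$model$goal$nu <- 0; cfg$model$assoc$nu <- 0; cfg$model$motor$nu <- 0
  m <- build_model(cfg, 1)
  w <- model_weights(m); w$dms[1, ] <- 0.5
  restore_weights(m, w)
  apply_lesion(m, "sns")
  for (i in 1:40) o <- step_model(m, numeric(0))
  da0 <- o$da_dls
  for (i in 1:100) o <- step_model(m, c(lever1 = 1))
  expect_equal(o$da_dls, da0, tolerance = 1e-6)
  # post-training PL lesion retains the valuation weights (expression intact)
  m2 <- build_model(default_config(), 1)
  restore_weights(m2, w)
  apply_lesion(m2, "pl")
  expect_identical(model_weights(m2)$nac, w$nac)
})

test_that("action selection thresholds, picks the maximum, and breaks ties fairly", {
  expect_identical(select_action(c(0.1, 0.1), 0.5), 0L)
  expect_identical(select_action(c(0.8, 0.1), 0.5), 1L)
  expect_identical(select_action(c(0.1, 0.8), 0.5), 2L)
  expect_identical(select_action(c(0.9, 0.8), 0.5), 1L)
  set.seed(123)
  picks <- replicate(10000, select_action(c(0.8, 0.8), 0.5))
  expect_equal(mean(picks == 1), 0.5, tolerance = 0.02)
})

test_that("channel silencing clamps the motor channel and reset restores it", {
  m <- build_model(default_config(), 1)
  w <- model_weights(m); w$dls[2, 2] <- 0.2
  restore_weights(m, w)
  silence_channel(m, 2)
  for (i in 1:30) {
    o <- step_model(m, c(lever2 = 1))
    expect_identical(o$motor$str[2], 0)
    expect_identical(o$motor$th[2], 0)
    expect_identical(o$mc[2], 0)
  }
  reset_model(m)
  o <- NULL
  for (i in 1:100) o <- step_model(m, c(lever2 = 1))
  expect_gt(o$motor$str[2], 0) # restored after the trial reset
})

test_that("reset zeroes states but preserves weights, clamps and the RNG stream", {
  m <- build_model(default_config(), 9)
  for (i in 1:100) step_model(m, c(lever1 = 1, food1 = as.numeric(i > 80)),
                              learning_on = TRUE)
  w_before <- model_weights(m)
  reset_model(m)
  expect_identical(model_weights(m), w_before)
  o <- step_model(m, numeric(0))
  expect_identical(o$bla, rep(0, 4))
  expect_identical(o$trace, rep(0, 4))
  reset_model(m); reset_model(m) # idempotent
  expect_identical(model_weights(m), w_before)
})

test_that("compiled unit trajectories match the R reference kernels", {
  cfg <- default_config()
  m <- build_model(cfg, 1)
  lh_cpp <- vta_cpp <- numeric(80)
  for (i in 1:80) {
    o <- step_model(m, c(food1 = 1))
    lh_cpp[i] <- o$lh; vta_cpp[i] <- o$vta
  }
  lh_p <- cfg$model$lh; vta_p <- cfg$model$vta
  s <- list(u_o = 0, u_i = 0, o = 0)
  v <- list(u = 0, v = max(tanh(vta_p$sigma * (0 - vta_p$theta)), 0))
  lh_r <- vta_r <- numeric(80)
  for (i in 1:80) {
    s <- step_onset(s, list(tau_o = lh_p$tau_o, tau_i = lh_p$tau_i),
                    input = lh_p$w_food * 1, dt = 0.05)
    lh_r[i] <- s$o
    v <- step_leaky(v, list(tau = vta_p$tau, sigma = vta_p$sigma,
                            theta = vta_p$theta),
                    input = vta_p$w_lh * s$o, dt = 0.05)
    vta_r[i] <- v$v
  }
  expect_equal(lh_cpp, lh_r, tolerance = 1e-12)
  expect_equal(vta_cpp, vta_r, tolerance = 1e-12)
})
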