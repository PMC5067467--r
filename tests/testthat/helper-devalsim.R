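# Shared helpers: reference integrators and scaled-down experiment configs.

# fine-step reference integration of the onset unit ODE pair
onset_reference <- function(input_fun, tau_o, tau_i, t_end, dt = 1e-4) {
  n <- ceiling(t_end / dt)
  u_o <- u_i <- 0
  t <- o <- numeric(n)
  for (k in seq_len(n)) {
    I <- input_fun((k - 1) * dt)
    u_o <- u_o + dt / tau_o * (-u_o + max(I - u_i, 0))
    u_i <- u_i + dt / tau_i * (-u_i + I)
    t[k] <- k * dt
    o[k] <- max(tanh(u_o), 0)
  }
  data.frame(t = t, o = o)
}

# textbook sum-of-squares one-way repeated-measures ANOVA (subjects x bins)
rm_anova_bruteforce <- function(m) {
  n_s <- nrow(m); n_b <- ncol(m)
  grand <- mean(m)
  ss_bin <- n_s * sum((colMeans(m) - grand)^2)
  ss_subj <- n_b * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_bin - ss_subj
  df1 <- n_b - 1
  df2 <- (n_b - 1) * (n_s - 1)
  F <- (ss_bin / df1) / (ss_err / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

# paired t by the textbook difference-score formula
paired_t_bruteforce <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# short protocol for structural protocol tests (not the study conditions)
tiny_config <- function(...) {
  experiment_config(default_config(), train_session_min = 2,
                    test_session_min = 1, n_reps = 2, ...)
}

# hand-set post-training weights of an intact simulated rat (demo/testing)
trained_demo_weights <- function() {
  W_bla <- matrix(0, 4, 4)
  W_bla[3, 1] <- 1.5; W_bla[4, 2] <- 1.5     # US_i <- CS_i
  W_nac <- matrix(0, 2, 4)
  W_nac[1, 3] <- 3; W_nac[2, 4] <- 3         # goal_i <- US_i
  W_nac[1, 4] <- 0.3; W_nac[2, 3] <- 0.3
  W_dms <- matrix(c(0.2, 0.05, 0.05, 0.2), 2, 2)
  W_dls <- matrix(c(0.2, 0.05, 0.05, 0.2), 2, 2)
  list(bla = W_bla, nac = W_nac, dms = W_dms, dls = W_dls)
}
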