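#' Default model and experiment configuration
#'
#' Returns the full parameter set of the simulated rat: unit time constants,
#' output-function slopes and thresholds for every bank, fixed connection
#' weights, learning-rule parameters, thalamic noise, and the operant-chamber
#' protocol constants. Every value can be overridden via [load_config()] or by
#' editing the returned list before [build_model()].
#'
#' The `model` section holds the network; the `experiment` section holds the
#' protocol (cycle length 0.05 s, 0.5 s action hold, 1 s reward delivery,
#' 15 s trial timeout, 20 min training sessions, 2 min extinction tests,
#' 10 learning-curve bins, 40 replicates).
#'
#' @return A nested named list with components `model` and `experiment`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg$model)
default_config <- function() {
  loop <- list(
    tau_str = 0.1, sigma_str = 1, theta_str = 0.2, iota = 1, delta = 3,
    tau_stn = 0.1, sigma_stn = 2, theta_stn = 0.1,
    tau_gpi = 0.1, sigma_gpi = 0.6, theta_gpi = -1.0,
    tau_th  = 0.1, sigma_th  = 2, theta_th  = -0.05, tau_n = 0.5, nu = 2.7,
    tau_ctx = 0.1, sigma_ctx = 2, theta_ctx = 0.1,
    w_cs = 0.6, w_ce = 0.5, w_se = 0.6, w_sg = 1.2,
    w_gt = 0.8, w_tc = 1.0, w_ct = 0.6, w_tt = 0.4
  )
  goal_loop <- loop
  goal_loop$w_sg <- 2.0; goal_loop$w_cs <- 0.9; goal_loop$w_ct <- 0.6
  goal_loop$tau_ctx <- 0.2; goal_loop$tau_th <- 0.1; goal_loop$theta_str <- 0.1; goal_loop$nu <- 3.8; goal_loop$w_gt <- 0.95
  goal_loop$w_tt <- 1.2; goal_loop$delta <- 1
  assoc_loop <- loop; assoc_loop$w_ct <- 1.0
  model <- list(
    goal = goal_loop, assoc = assoc_loop, motor = loop,
    bla = list(
      tau_o = 0.1, tau_i = 3.0, w_lever = 1, w_food = 1.5, w_sat = 10,
      trace_alpha = 1, trace_tau = 4,
      eta = 4, theta_da = 0.3, max_w = 1.5
    ),
    lh  = list(tau_o = 0.05, tau_i = 1.0, w_food = 1),
    ppn = list(tau_o = 0.05, tau_i = 1.0, w_food = 1),
    vta = list(tau = 0.1, sigma = 2, theta = 0.1, w_lh = 1.5),
    snpc = list(
      tau_e = 0.1, sigma_e = 2, theta_e = -0.5,
      tau_i = 0.8, sigma_i = 2, theta_i = -0.5,
      w_ppn = 2, w_inh = 0.55, w_spiral = 0.8
    ),
    nac = list(eta = 0.1, theta_da = 0.3, theta_str = 0.75, theta_inp = 0.6, w_cap = 3),
    dms = list(eta = 0.05, theta_da = 0.8, theta_str = 0.4, theta_inp = 0.5, w_cap = 0.2),
    dls = list(eta = 0.05, theta_da = 0.8, theta_str = 0.4, theta_inp = 0.5, w_cap = 0.2),
    cc  = list(w_pl_actx = 0.05, w_actx_mc = 0.5, w_mc_actx = 0.4, w_actx_pl = 0.4)
  )
  experiment <- list(
    cycle_s = 0.05, substeps = 1,
    hold_s = 0.5, reward_s = 1.0, timeout_s = 15, silence_s = 2,
    train_session_min = 20, test_session_min = 2,
    n_bins = 10, n_reps = 40, base_seed = 1,
    theta_mc = 0.5, variant = "two-manipulanda"
  )
  list(model = model, experiment = experiment)
}

# recursively flatten the model section into the named vector the C++ core expects
flatten_model <- function(config) {
  m <- config$model
  ex <- config$experiment
  out <- c(
    cycle_s = ex$cycle_s, substeps = ex$substeps,
    one_lever = as.numeric(identical(ex$variant, "one-manipulandum"))
  )
  for (sec in names(m)) {
    v <- unlist(m[[sec]])
    names(v) <- paste(sec, names(v), sep = ".")
    out <- c(out, v)
  }
  out
}

check_positive <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop("configuration error: '", key, "' must be a positive number", call. = FALSE)
}

check_nonneg <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
    stop("configuration error: '", key, "' must be a non-negative number", call. = FALSE)
}

#' Validate a configuration list
#'
#' Checks that every parameter the model needs is present and within its
#' declared range (time constants and slopes positive, gains and learning
#' rates non-negative, the action hold an integer multiple of the cycle).
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param config A nested list shaped like [default_config()].
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  for (top in names(config)) {
    if (!top %in% names(ref))
      stop("configuration error: unknown section '", top, "'", call. = FALSE)
    for (sec in names(config[[top]])) {
      if (!sec %in% names(ref[[top]]))
        stop("configuration error: unknown key '", top, ".", sec, "'", call. = FALSE)
      if (is.list(ref[[top]][[sec]])) {
        extra <- setdiff(names(config[[top]][[sec]]), names(ref[[top]][[sec]]))
        if (length(extra))
          stop("configuration error: unknown key '", top, ".", sec, ".",
               extra[1], "'", call. = FALSE)
      }
    }
  }
  ex <- config$experiment
  for (key in c("cycle_s", "hold_s", "reward_s", "timeout_s",
                "train_session_min", "test_session_min"))
    check_positive(ex[[key]], paste0("experiment.", key))
  if (ex$substeps < 1 || ex$substeps != round(ex$substeps))
    stop("configuration error: 'experiment.substeps' must be an integer >= 1",
         call. = FALSE)
  hold_cycles <- ex$hold_s / ex$cycle_s
  if (abs(hold_cycles - round(hold_cycles)) > 1e-9)
    stop("configuration error: 'experiment.hold_s' must be an integer multiple of 'experiment.cycle_s'",
         call. = FALSE)
  if (!ex$variant %in% c("two-manipulanda", "one-manipulandum"))
    stop("configuration error: 'experiment.variant' must be 'two-manipulanda' or 'one-manipulandum'",
         call. = FALSE)
  m <- config$model
  for (lp in c("goal", "assoc", "motor")) {
    for (key in c("tau_str", "tau_stn", "tau_gpi", "tau_th", "tau_ctx", "tau_n",
                  "sigma_str", "sigma_stn", "sigma_gpi", "sigma_th", "sigma_ctx"))
      check_positive(m[[lp]][[key]], paste0("model.", lp, ".", key))
    for (key in c("iota", "delta", "nu"))
      check_nonneg(m[[lp]][[key]], paste0("model.", lp, ".", key))
  }
  for (key in c("tau_o", "tau_i", "trace_alpha", "trace_tau", "max_w"))
    check_positive(m$bla[[key]], paste0("model.bla.", key))
  for (sec in c("lh", "ppn"))
    for (key in c("tau_o", "tau_i"))
      check_positive(m[[sec]][[key]], paste0("model.", sec, ".", key))
  for (key in c("tau", "sigma")) check_positive(m$vta[[key]], paste0("model.vta.", key))
  for (key in c("tau_e", "tau_i", "sigma_e", "sigma_i"))
    check_positive(m$snpc[[key]], paste0("model.snpc.", key))
  for (key in c("w_ppn", "w_inh", "w_spiral"))
    check_nonneg(m$snpc[[key]], paste0("model.snpc.", key))
  if (m$bla$tau_i < m$bla$tau_o)
    stop("configuration error: 'model.bla.tau_i' must be >= 'model.bla.tau_o' (onset transient)",
         call. = FALSE)
  check_nonneg(m$bla$eta, "model.bla.eta")
  for (proj in c("nac", "dms", "dls")) {
    check_nonneg(m[[proj]]$eta, paste0("model.", proj, ".eta"))
    for (key in c("theta_da", "theta_str", "theta_inp"))
      check_nonneg(m[[proj]][[key]], paste0("model.", proj, ".", key))
    check_positive(m[[proj]]$w_cap, paste0("model.", proj, ".w_cap"))
  }
  invisible(config)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a configuration file
#'
#' Reads a YAML parameter file, fills unspecified values from
#' [default_config()], validates the result and records which values were
#' defaulted.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list with attribute `"defaulted"` naming
#'   the top-level sections that were left at their default values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  defaulted <- names(cfg)
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("configuration error: file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      cfg <- merge_config(cfg, user)
      defaulted <- setdiff(defaulted, names(user))
    }
  }
  validate_config(cfg)
  attr(cfg, "defaulted") <- defaulted
  cfg
}

#' Write a configuration to a YAML file
#'
#' Round-trips with [load_config()]: dumping and re-loading yields an
#' identical parameter set.
#'
#' @param config A configuration list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  attr(config, "defaulted") <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}
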