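#' Experiment configuration helper
#'
#' Convenience wrapper to override protocol constants (replicates, seeds,
#' variant, session durations) on top of [default_config()].
#'
#' @param config Base configuration.
#' @param ... Named experiment fields to override (e.g. `n_reps = 10`,
#'   `variant = "one-manipulandum"`, `base_seed = 7`).
#' @return The updated configuration.
#' @export
experiment_config <- function(config = default_config(), ...) {
  over <- list(...)
  if (length(over)) config$experiment <- merge_config(config$experiment, over)
  validate_config(config)
  config
}

session_env <- function(kind, variant) {
  one <- identical(variant, "one-manipulandum")
  # `effective`: actions with an environmental consequence this session; the
  # rest trigger the channel switch-off. In extinction tests every available
  # action is effective but unrewarded.
  switch(kind,
    "train1" = list(present = c(TRUE, FALSE), effective = c(TRUE, FALSE),
                    rewarded = c(TRUE, FALSE), sat = c(0, 0), train = TRUE),
    "train2" = list(present = if (one) c(TRUE, FALSE) else c(FALSE, TRUE),
                    effective = c(FALSE, TRUE),
                    rewarded = c(FALSE, TRUE), sat = c(0, 0), train = TRUE),
    "test-ND" = list(present = if (one) c(TRUE, FALSE) else c(TRUE, TRUE),
                     effective = c(TRUE, TRUE),
                     rewarded = c(FALSE, FALSE), sat = c(0, 0), train = FALSE),
    "test-D" = list(present = if (one) c(TRUE, FALSE) else c(TRUE, TRUE),
                    effective = c(TRUE, TRUE),
                    rewarded = c(FALSE, FALSE), sat = c(0, 1), train = FALSE),
    stop("unknown session kind: ", kind, call. = FALSE)
  )
}

#' Run a single trial
#'
#' Cycles the model until a rewarded press completes its 1 s delivery window
#' or the trial times out (15 s by default). A press is the completion of a
#' 0.5 s hold (10 consecutive supra-threshold cycles of the same action); an
#' interruption restarts the hold. An action on an absent manipulandum is
#' ineffective and switches its motor channel off for the rest of the trial.
#' Units are reset at trial end; weights persist.
#'
#' @param model An `ide_model`.
#' @param present Logical length-2: which manipulanda are present.
#' @param rewarded Logical length-2: which actions deliver food.
#' @param sat Numeric length-2 satiation inputs.
#' @param learning_on Logical.
#' @return A list with `presses` (data.frame of action and completion time in
#'   seconds), `n_press`, `rewards`, `end` (`"reward"` or `"timeout"`) and
#'   `duration_s`.
#' @export
run_trial <- function(model, present, rewarded = c(FALSE, FALSE),
                      sat = c(0, 0), learning_on = TRUE, effective = present) {
  stopifnot(inherits(model, "ide_model"))
  ex <- model$config$experiment
  res <- net_run_trial(model$ptr, as.logical(present), as.logical(effective),
                       as.logical(rewarded),
                       as.numeric(sat), isTRUE(learning_on),
                       as.integer(round(ex$timeout_s / ex$cycle_s)),
                       as.integer(round(ex$hold_s / ex$cycle_s)),
                       as.integer(round(ex$reward_s / ex$cycle_s)),
                       ex$theta_mc, as.integer(ex$silence_s))
  list(presses = data.frame(action = res$press_action,
                            time_s = (res$press_cycle + 1) * ex$cycle_s),
       n_press = res$n_press, rewards = res$rewards,
       end = res$end, duration_s = res$cycles * ex$cycle_s)
}

#' Run one session
#'
#' Executes trials back-to-back until the session clock expires (training:
#' 20 min; tests: 2 min). Learning stays enabled in the extinction tests:
#' without reward there is no phasic dopamine, so the plasticity gates stay
#' closed and weights cannot move.
#'
#' @param model An `ide_model`.
#' @param kind One of `"train1"`, `"train2"`, `"test-ND"`, `"test-D"`.
#' @return A `session_log`: list with `kind`, `presses` (action, absolute
#'   completion time in seconds, trial index), `trials` (per-trial records)
#'   and `duration_s`.
#' @export
run_session <- function(model, kind) {
  stopifnot(inherits(model, "ide_model"))
  ex <- model$config$experiment
  env <- session_env(kind, ex$variant)
  mins <- if (env$train) ex$train_session_min else ex$test_session_min
  session_cycles <- as.integer(round(mins * 60 / ex$cycle_s))
  res <- net_run_session(model$ptr, env$present, env$effective, env$rewarded,
                         as.numeric(env$sat), TRUE, session_cycles,
                         as.integer(round(ex$timeout_s / ex$cycle_s)),
                         as.integer(round(ex$hold_s / ex$cycle_s)),
                         as.integer(round(ex$reward_s / ex$cycle_s)),
                         ex$theta_mc, as.integer(ex$silence_s))
  structure(list(
    kind = kind,
    presses = data.frame(action = res$press_action,
                         time_s = (res$press_cycle + 1) * ex$cycle_s,
                         trial = res$press_trial),
    trials = data.frame(trial = res$trial, presses_1 = res$p1,
                        presses_2 = res$p2, rewards_1 = res$r1,
                        rewards_2 = res$r2,
                        duration_s = res$trial_cycles * ex$cycle_s,
                        end = res$end),
    duration_s = mins * 60
  ), class = "session_log")
}

#' Condition specification
#'
#' Maps the experiment condition labels to lesion specs: `CONTROL` (intact),
#' pre- or post-training lesions of BLA/IC, NAc, DMS, PL, and the pre/post
#' disconnection of the striato-nigro-striatal spirals (`SNS-pre`,
#' `SNS-post`).
#'
#' @param label Condition label, e.g. `"CONTROL"`, `"BLA/IC-pre"`,
#'   `"PL-post"`, `"SNS-pre"`.
#' @return An object of class `condition_spec` with fields `label` and
#'   `lesion` (`NULL` for CONTROL).
#' @export
condition_spec <- function(label) {
  known <- c("CONTROL",
             "BLA/IC-pre", "NAc-pre", "DMS-pre", "PL-pre",
             "BLA-post", "NAc-post", "DMS-post", "PL-post",
             "SNS-pre", "SNS-post")
  label <- match.arg(label, known)
  lesion <- NULL
  if (label != "CONTROL") {
    parts <- strsplit(label, "-")[[1]]
    timing <- parts[length(parts)]
    target <- switch(paste(parts[-length(parts)], collapse = "-"),
                     "BLA/IC" = "bla", "BLA" = "bla", "NAc" = "nac",
                     "DMS" = "dms", "PL" = "pl", "SNS" = "sns")
    lesion <- lesion_spec(target, timing)
  }
  structure(list(label = label, lesion = lesion), class = "condition_spec")
}

#' Run one simulated rat
#'
#' Builds a model from `seed`, applies any pre-training lesion, runs the two
#' 20-min training sessions (manipulandum 1 with food 1, then manipulandum 2
#' with food 2; in the one-manipulandum variant the two sessions reward the
#' two different actions on the same manipulandum), snapshots the trained
#' weights, applies any post-training lesion, and runs the two 2-min
#' extinction tests (first with no satiation, then with food 2 satiated).
#'
#' @param condition A [condition_spec()] or condition label.
#' @param config Configuration list.
#' @param seed Integer seed for this replicate.
#' @return A list with `condition`, `seed`, `train` (two session logs),
#'   `test` (ND and D session logs) and `weights` (post-training snapshot).
#' @export
run_replicate <- function(condition, config = default_config(), seed = 1L) {
  if (!inherits(condition, "condition_spec"))
    condition <- condition_spec(condition)
  model <- build_model(config, seed = seed)
  les <- condition$lesion
  if (!is.null(les) && les$timing == "pre") apply_lesion(model, les)
  train <- list(run_session(model, "train1"), run_session(model, "train2"))
  weights <- model_weights(model)
  if (!is.null(les) && les$timing == "post") apply_lesion(model, les)
  test <- list(nd = run_session(model, "test-ND"),
               d = run_session(model, "test-D"))
  list(condition = condition$label, seed = seed,
       train = train, test = test, weights = weights)
}

#' Run a battery of conditions
#'
#' For each condition, runs `n_reps` replicates with seeds
#' `base_seed + 0 .. base_seed + n_reps - 1` (the same seeds across
#' conditions, so conditions are matched) and aggregates per-bin training
#' press counts and per-test press counts per action.
#'
#' @param conditions Character vector of condition labels or list of
#'   [condition_spec()]s.
#' @param config Configuration list (its `experiment$n_reps`,
#'   `experiment$base_seed` and `experiment$n_bins` drive the battery).
#' @param progress Logical; print one line per condition.
#' @return An object of class `ide_battery`: per condition a list with
#'   `bins` (replicate-x-session series in rows, bins in columns), `nd` and
#'   `d` (replicate rows, action-1/action-2 press counts).
#' @export
run_battery <- function(conditions, config = default_config(), progress = FALSE) {
  ex <- config$experiment
  seeds <- ex$base_seed + seq_len(ex$n_reps) - 1L
  out <- list()
  for (cond in conditions) {
    spec <- if (inherits(cond, "condition_spec")) cond else condition_spec(cond)
    bins <- NULL; nd <- NULL; d <- NULL
    for (s in seeds) {
      rep <- run_replicate(spec, config, seed = s)
      bins <- rbind(bins,
                    bin_press_counts(rep$train[[1]], ex$n_bins),
                    bin_press_counts(rep$train[[2]], ex$n_bins))
      nd <- rbind(nd, session_counts(rep$test$nd))
      d <- rbind(d, session_counts(rep$test$d))
    }
    out[[spec$label]] <- list(bins = bins, nd = nd, d = d)
    if (progress)
      message(sprintf("%-11s final bin %.2f | ND %5.1f/%5.1f | D %5.1f/%5.1f",
                      spec$label, mean(bins[, ncol(bins)]),
                      mean(nd[, 1]), mean(nd[, 2]), mean(d[, 1]), mean(d[, 2])))
  }
  structure(list(conditions = out, config = config), class = "ide_battery")
}

session_counts <- function(log) {
  c(a1 = sum(log$presses$action == 1), a2 = sum(log$presses$action == 2))
}

#' @export
print.ide_battery <- function(x, ...) {
  cat("<ide_battery>", length(x$conditions), "condition(s),",
      x$config$experiment$n_reps, "replicates each\n")
  for (nm in names(x$conditions)) {
    cc <- x$conditions[[nm]]
    cat(sprintf("  %-11s final bin %5.2f | ND %5.2f vs %5.2f | D %5.2f vs %5.2f\n",
                nm, mean(cc$bins[, ncol(cc$bins)]),
                mean(cc$nd[, 1]), mean(cc$nd[, 2]),
                mean(cc$d[, 1]), mean(cc$d[, 2])))
  }
  invisible(x)
}

#' Summarize a battery: tables and devaluation verdicts
#'
#' Produces the training table (bin means and the one-factor repeated
#' measures ANOVA per condition) and the test table (mean presses per action,
#' paired t-tests for both extinction tests, and the devaluation-effect
#' verdict).
#'
#' @param object An `ide_battery`.
#' @param alpha Significance level for the devaluation-effect rule.
#' @param ... Unused.
#' @return A list of class `ide_battery_summary` with data.frames `training`
#'   and `test`.
#' @export
summary.ide_battery <- function(object, alpha = 0.05, ...) {
  training <- NULL; test <- NULL
  for (nm in names(object$conditions)) {
    cc <- object$conditions[[nm]]
    an <- repeated_anova_bins(cc$bins)
    row <- data.frame(condition = nm, t(colMeans(cc$bins)),
                      F = an$F, df1 = an$df1, df2 = an$df2, p = an$p)
    names(row)[2:(1 + ncol(cc$bins))] <- paste0("bin", seq_len(ncol(cc$bins)))
    training <- rbind(training, row)
    t_nd <- paired_t(cc$nd[, 1], cc$nd[, 2])
    t_d <- paired_t(cc$d[, 1], cc$d[, 2])
    verdict <- assess_ide(t_nd, t_d, alpha)
    test <- rbind(test, data.frame(
      condition = nm,
      nd_a1 = mean(cc$nd[, 1]), nd_a2 = mean(cc$nd[, 2]),
      nd_t = t_nd$t, nd_df = t_nd$df, nd_p = t_nd$p,
      d_a1 = mean(cc$d[, 1]), d_a2 = mean(cc$d[, 2]),
      d_t = t_d$t, d_df = t_d$df, d_p = t_d$p,
      ide = verdict$present))
  }
  structure(list(training = training, test = test, alpha = alpha),
            class = "ide_battery_summary")
}

#' @export
print.ide_battery_summary <- function(x, ...) {
  cat("Training (mean presses per 2-min bin; one-factor repeated ANOVA)\n")
  tr <- x$training
  tr[-1] <- lapply(tr[-1], function(col) round(col, 3))
  print(tr, row.names = FALSE)
  cat("\nExtinction tests (mean presses; paired t; devaluation effect at alpha =",
      x$alpha, ")\n")
  te <- x$test
  num <- vapply(te, is.numeric, logical(1))
  te[num] <- lapply(te[num], function(col) signif(col, 4))
  print(te, row.names = FALSE)
  invisible(x)
}

#' Plot battery results
#'
#' Grouped bar charts of mean presses per action in the non-devalued (ND) and
#' devalued (D) extinction tests, one panel per condition, plus the binned
#' training curves.
#'
#' @param x An `ide_battery`.
#' @param which `"test"` (bar charts) or `"training"` (learning curves).
#' @param ... Passed to the underlying graphics calls.
#' @export
plot.ide_battery <- function(x, which = c("test", "training"), ...) {
  which <- match.arg(which)
  conds <- names(x$conditions)
  if (which == "test") {
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(conds)),
                         mar = c(2.5, 3.5, 2, 0.5))
    on.exit(graphics::par(old))
    for (nm in conds) {
      cc <- x$conditions[[nm]]
      h <- rbind(c(mean(cc$nd[, 1]), mean(cc$d[, 1])),
                 c(mean(cc$nd[, 2]), mean(cc$d[, 2])))
      graphics::barplot(h, beside = TRUE, names.arg = c("ND", "D"),
                        col = c("grey30", "grey70"), main = nm,
                        ylab = "presses / 2 min", ...)
      graphics::legend("topright", c("L1", "L2"), fill = c("grey30", "grey70"),
                       bty = "n", cex = 0.8)
    }
  } else {
    curves <- vapply(x$conditions, function(cc) colMeans(cc$bins),
                     numeric(ncol(x$conditions[[1]]$bins)))
    graphics::matplot(curves, type = "b", pch = 19, lty = 1,
                      xlab = "training bin (2 min)", ylab = "mean presses", ...)
    graphics::legend("bottomright", conds, col = seq_along(conds), lty = 1,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
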