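#' Build the wired network
#'
#' Assembles the full model: three basal ganglia-thalamo-cortical loops
#' (goal: NAc-PL; associative: DMS-PPC/PFCd; motor: DLS-MC, two channels
#' each), the four-unit BLA/IC valuation bank with its plastic lateral
#' connections, the dopamine system (LH to VTA, PPN to SNpc, two SNpc modules
#' with per-channel excitatory/slow-inhibitory couples, channel-preserving
#' striato-nigro-striatal spirals), the fixed cortico-cortical pathway
#' PL to associative cortex to MC, and the plastic out-of-loop striatal input
#' projections. All plastic weights start at exactly zero.
#'
#' The returned object holds the simulation state by reference (an external
#' pointer into the compiled core): functions such as [step_model()],
#' [apply_lesion()] and [run_session()] advance or modify the model in
#' place, as is usual for stateful simulator handles.
#'
#' @param config A configuration list from [default_config()] or
#'   [load_config()].
#' @param seed Integer seed; the model owns an R RNG stream seeded here, used
#'   for thalamic noise and action tie-breaks.
#' @return An object of class `ide_model`.
#' @export
#' @examples
#' m <- build_model(default_config(), seed = 1)
#' out <- step_model(m, stimuli = c(lever1 = 1, lever2 = 0, food1 = 0,
#'                                  food2 = 0, sat1 = 0, sat2 = 0))
#' out$mc
build_model <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  set.seed(seed)
  ptr <- net_build(flatten_model(config))
  structure(list(ptr = ptr, config = config, seed = seed,
                 lesions = character(0)),
            class = "ide_model")
}

#' @export
print.ide_model <- function(x, ...) {
  ex <- x$config$experiment
  cat("<ide_model> basal ganglia-amygdala devaluation network\n")
  cat("  variant:", ex$variant, "| cycle:", ex$cycle_s, "s | substeps:",
      ex$substeps, "\n")
  cat("  seed:", x$seed, "\n")
  if (length(x$lesions)) cat("  lesions:", paste(x$lesions, collapse = ", "), "\n")
  w <- net_get_weights(x$ptr)
  cat(sprintf("  plastic weight mass: bla %.3f | nac %.3f | dms %.3f | dls %.3f\n",
              sum(w$bla), sum(w$nac), sum(w$dms), sum(w$dls)))
  invisible(x)
}

as_stimuli <- function(stimuli) {
  full <- c(lever1 = 0, lever2 = 0, food1 = 0, food2 = 0, sat1 = 0, sat2 = 0)
  if (is.null(names(stimuli)) && length(stimuli) == 6) return(as.numeric(stimuli))
  bad <- setdiff(names(stimuli), names(full))
  if (length(bad)) stop("unknown stimulus: ", bad[1], call. = FALSE)
  full[names(stimuli)] <- stimuli
  as.numeric(full)
}

#' Advance the model by one environment cycle
#'
#' Steps the whole network once (0.05 s by default): inputs, BLA/IC and
#' dopamine sources, then the goal, associative and motor loops in order,
#' then activity traces and (if `learning_on`) the two Hebbian rules, with
#' lesion clamps re-applied last.
#'
#' @param model An [build_model()] object.
#' @param stimuli Named binary vector with any of `lever1, lever2, food1,
#'   food2, sat1, sat2` (missing entries are 0).
#' @param learning_on Logical; apply the plasticity rules this cycle.
#' @return A named list of region activations (`bla`, `vta`, `da_dms`,
#'   `da_dls`, per-loop `str`/`stn`/`gpi`/`th`/`ctx`, and `mc`, the
#'   motor-cortex outputs).
#' @export
step_model <- function(model, stimuli = numeric(0), learning_on = FALSE) {
  stopifnot(inherits(model, "ide_model"))
  net_step(model$ptr, as_stimuli(stimuli), isTRUE(learning_on))
}

#' Select an action from motor-cortex outputs
#'
#' Returns 0 (no action) unless an MC unit exceeds `theta_mc`; when both
#' exceed it the larger wins and exact ties are broken uniformly at random.
#'
#' @param mc_outputs Numeric vector of the 2 motor-cortex activations.
#' @param theta_mc Action threshold.
#' @return 0, 1 or 2.
#' @export
select_action <- function(mc_outputs, theta_mc) {
  stopifnot(length(mc_outputs) == 2)
  above <- mc_outputs > theta_mc
  if (!any(above)) return(0L)
  if (all(above) && mc_outputs[1] == mc_outputs[2])
    return(if (stats::runif(1) < 0.5) 1L else 2L)
  which.max(ifelse(above, mc_outputs, -Inf))
}

#' Lesion specification
#'
#' @param target One of `"bla"`, `"nac"`, `"dms"`, `"pl"` (structure lesions:
#'   unit activations permanently clamped to zero) or `"sns"` (disconnection
#'   of the striato-nigro-striatal spiral projections: their weights are
#'   zeroed and frozen).
#' @param timing `"pre"` (before training) or `"post"` (after training).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(target, timing = c("pre", "post")) {
  target <- match.arg(target, c("bla", "nac", "dms", "pl", "sns"))
  timing <- match.arg(timing)
  structure(list(target = target, timing = timing), class = "lesion_spec")
}

#' Apply a lesion or disconnection
#'
#' Structure lesions add a permanent output clamp (zero on every subsequent
#' cycle); the spiral disconnection zeroes the NAc-to-SNpc and DMS-to-SNpc
#' projections. Clamps are absorbing: nothing un-clamps short of rebuilding
#' the model.
#'
#' @param model An `ide_model`.
#' @param spec A [lesion_spec()] or a target string.
#' @return The model, invisibly (modified in place).
#' @export
apply_lesion <- function(model, spec) {
  stopifnot(inherits(model, "ide_model"))
  target <- if (inherits(spec, "lesion_spec")) spec$target else
    match.arg(spec, c("bla", "nac", "dms", "pl", "sns"))
  net_set_lesion(model$ptr, target)
  model$lesions <- union(model$lesions, target)
  invisible(model)
}

#' Reset the model state between trials
#'
#' Zeroes all unit activations, traces and noise states; connection weights,
#' lesion clamps and the RNG stream are preserved.
#'
#' @param model An `ide_model`.
#' @return The model, invisibly.
#' @export
reset_model <- function(model) {
  stopifnot(inherits(model, "ide_model"))
  net_reset(model$ptr)
  invisible(model)
}

#' Switch off a motor-loop channel
#'
#' Clamps the channel's striatal, STN, GPi/SNpr, thalamic and cortical units
#' to zero, mimicking the lack of environmental feedback after an action on
#' an absent manipulandum.
#'
#' @param model An `ide_model`.
#' @param channel 1 or 2.
#' @param duration Cycles to keep the clamp, or `-1` for the rest of the
#'   trial (cleared by [reset_model()]).
#' @return The model, invisibly.
#' @export
silence_channel <- function(model, channel, duration = -1L) {
  stopifnot(inherits(model, "ide_model"))
  net_silence(model$ptr, as.integer(channel), as.integer(duration))
  invisible(model)
}

#' Extract or restore the plastic weight matrices
#'
#' `model_weights` returns the four plastic matrices (BLA/IC lateral 4x4,
#' BLA/IC-to-NAc 2x4, levers-to-DMS 2x2, levers-to-DLS 2x2).
#' `restore_weights` writes them back, so a trained model can be checkpointed
#' between the training and test phases. `write_weights`/`read_weights`
#' round-trip the snapshot through plain CSV.
#'
#' @param model An `ide_model`.
#' @param weights A list as returned by `model_weights`.
#' @param path Directory for the CSV snapshot.
#' @return `model_weights`/`read_weights`: a named list of matrices.
#' @export
model_weights <- function(model) {
  stopifnot(inherits(model, "ide_model"))
  net_get_weights(model$ptr)
}

#' @rdname model_weights
#' @export
restore_weights <- function(model, weights) {
  stopifnot(inherits(model, "ide_model"))
  net_set_weights(model$ptr, weights)
  invisible(model)
}

#' @rdname model_weights
#' @export
write_weights <- function(weights, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(weights))
    utils::write.csv(weights[[nm]], file.path(path, paste0("w_", nm, ".csv")),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname model_weights
#' @export
read_weights <- function(path) {
  out <- lapply(c("bla", "nac", "dms", "dls"), function(nm)
    as.matrix(utils::read.csv(file.path(path, paste0("w_", nm, ".csv")))))
  names(out) <- c("bla", "nac", "dms", "dls")
  lapply(out, unname)
}
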