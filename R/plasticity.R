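#' Activity traces and dopamine-gated Hebbian learning rules
#'
#' The model uses two plasticity rules, both gated by phasic dopamine and
#' both producing only non-negative weight increments (no extinction is
#' modeled, so plastic weights are monotonically non-decreasing).
#'
#' `step_trace` advances the slow activity trace
#' \eqn{\tau_t \dot t = -t + \alpha o} that makes learning sensitive to the
#' *timing* of unit activations, and records its rate of change.
#'
#' `bla_weight_update` is the differential Hebbian rule of the amygdala /
#' insular-cortex bank: a weight grows only when dopamine exceeds its gate
#' threshold *and* the presynaptic trace is falling while the postsynaptic
#' trace is rising — i.e. only a forward (CS-then-US) sequence is learned —
#' with a soft ceiling `max_w_bla`.
#'
#' `striatal_weight_update` is the three-factor rule training out-of-loop
#' cortical inputs onto striatal units: increment proportional to the
#' supra-threshold parts of dopamine, striatal activation and input
#' activation. Weights are clipped to `[0, w_cap]` by [apply_updates()].
#'
#' @param state Trace state `list(t =, t_dot =)`.
#' @param params Rule parameters: for `step_trace` `list(alpha, tau_t)`; for
#'   `bla_weight_update` `list(eta_b, theta_da_bla, max_w_bla)`; for
#'   `striatal_weight_update`
#'   `list(eta_str, theta_da_str, theta_str, theta_inp_str)`.
#' @param o Unit output activation (non-negative).
#' @param dt Step size in seconds.
#' @param w Current weight (scalar).
#' @param pre,post Trace states of the pre- and post-synaptic units.
#' @param da Dopamine level.
#' @param v_inp,v_str Input and striatal activations in `[0, 1)`.
#' @return `step_trace`: the advanced trace state. The update rules: the
#'   weight increment (always `>= 0`).
#' @name plasticity-rules
#' @examples
#' # only a pre-falling / post-rising trace pair learns
#' p <- list(eta_b = 1, theta_da_bla = 0, max_w_bla = 1)
#' bla_weight_update(0, pre = list(t = 1, t_dot = -0.3),
#'                   post = list(t = 0.5, t_dot = 0.2), da = 0.5, params = p)
NULL

#' @rdname plasticity-rules
#' @export
step_trace <- function(state, params, o, dt) {
  stopifnot(o >= 0, dt > 0)
  t_new <- state$t + dt / params$tau_t * (-state$t + params$alpha * o)
  list(t = t_new, t_dot = (t_new - state$t) / dt)
}

#' @rdname plasticity-rules
#' @export
bla_weight_update <- function(w, pre, post, da, params) {
  stopifnot(w <= params$max_w_bla)
  params$eta_b * relu(da - params$theta_da_bla) * relu(post$t_dot) *
    relu(-pre$t_dot) * (params$max_w_bla - w)
}

#' @rdname plasticity-rules
#' @export
striatal_weight_update <- function(w, v_inp, v_str, da, params) {
  params$eta_str * relu(da - params$theta_da_str) *
    relu(v_str - params$theta_str) * relu(v_inp - params$theta_inp_str)
}

#' Plastic projection container
#'
#' A weight matrix (post x pre) with its learning rule, bounds and frozen
#' flag. Hardwired pathways are represented as frozen projections: applying
#' an update to them is a contract violation.
#'
#' @param w Numeric weight matrix, post-synaptic units in rows.
#' @param rule Learning rule label, `"bla"` or `"striatal"`.
#' @param params Rule parameter list (see [plasticity-rules]).
#' @param frozen Logical; frozen projections never change.
#' @param ceiling Upper bound applied elementwise (defaults to the rule's
#'   ceiling, `Inf` if none).
#' @return An object of class `plastic_projection`.
#' @export
plastic_projection <- function(w, rule = c("striatal", "bla"), params = list(),
                               frozen = FALSE, ceiling = NULL) {
  rule <- match.arg(rule)
  if (is.null(ceiling))
    ceiling <- switch(rule,
                      bla = params$max_w_bla %||% Inf,
                      striatal = params$w_cap %||% params$max_w %||% Inf)
  structure(list(w = as.matrix(w), rule = rule, params = params,
                 frozen = frozen, ceiling = ceiling),
            class = "plastic_projection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply weight increments to a plastic projection
#'
#' Adds the increments and clips elementwise to `[0, ceiling]`. Targeting a
#' frozen projection is an error.
#'
#' @param proj A [plastic_projection()].
#' @param increments Matrix of weight increments, same shape as `proj$w`.
#' @return The updated projection.
#' @export
apply_updates <- function(proj, increments) {
  stopifnot(inherits(proj, "plastic_projection"))
  if (proj$frozen)
    stop("cannot update a frozen projection", call. = FALSE)
  if (!all(dim(proj$w) == dim(as.matrix(increments))))
    stop("increment shape does not match the weight matrix", call. = FALSE)
  proj$w <- pmin(pmax(proj$w + increments, 0), proj$ceiling)
  proj
}
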