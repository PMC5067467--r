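#' Unit dynamics: leaky, striatal and onset rate units, thalamic noise
#'
#' These functions advance single model units by one forward-Euler step and
#' are the reference kernels for the compiled network core. A leaky unit
#' integrates its input through \eqn{\tau \dot u = -u + I} and emits
#' \eqn{v = [\tanh(\sigma (u - \theta))]^+}, so activations always lie in
#' \eqn{[0, 1)}. A striatal unit is a leaky unit whose input is scaled by a
#' dopamine-dependent gain \eqn{(\iota + \delta \, da)}. An onset unit couples
#' an excitatory and an inhibitory population so that a sustained input
#' produces only a transient (phasic) response. The thalamic noise is a
#' decaying moving average of uniform draws.
#'
#' @param state For `step_leaky`/`step_striatal`: `list(u =, v =)`. For
#'   `step_onset`: `list(u_o =, u_i =, o =)`. For `step_noise`:
#'   `list(n =, z =)`.
#' @param params For `step_leaky`: `list(tau, sigma, theta)`. `step_striatal`
#'   additionally needs `iota` and `delta`. For `step_onset`:
#'   `list(tau_o, tau_i)`. For `step_noise`: `list(tau_n, nu)`.
#' @param input Summed weighted input \eqn{I} reaching the unit.
#' @param da Dopamine level (non-negative).
#' @param dt Step size in seconds (> 0).
#' @param z Optional uniform draw on \eqn{[-0.5, 0.5]}; drawn from the R RNG
#'   when omitted.
#' @return The advanced state, same shape as `state`.
#' @name unit-dynamics
#' @examples
#' s <- list(u = 0, v = 0)
#' p <- list(tau = 0.1, sigma = 1, theta = 0)
#' step_leaky(s, p, input = 1, dt = 0.05)$u  # 0.5 after one Euler step
NULL

check_step <- function(input, dt) {
  if (!is.finite(input))
    stop("non-finite input to unit update: unstable configuration", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
}

relu <- function(x) pmax(x, 0)

#' @rdname unit-dynamics
#' @export
step_leaky <- function(state, params, input, dt) {
  check_step(input, dt)
  u <- state$u + dt / params$tau * (-state$u + input)
  list(u = u, v = relu(tanh(params$sigma * (u - params$theta))))
}

#' @rdname unit-dynamics
#' @export
step_striatal <- function(state, params, input, da, dt) {
  stopifnot(da >= 0)
  step_leaky(state, params, (params$iota + params$delta * da) * input, dt)
}

#' @rdname unit-dynamics
#' @export
step_onset <- function(state, params, input, dt) {
  check_step(input, dt)
  u_o <- state$u_o + dt / params$tau_o * (-state$u_o + relu(input - state$u_i))
  u_i <- state$u_i + dt / params$tau_i * (-state$u_i + input)
  list(u_o = u_o, u_i = u_i, o = relu(tanh(u_o)))
}

#' @rdname unit-dynamics
#' @export
step_noise <- function(state, params, dt, z = NULL) {
  if (is.null(z)) z <- stats::runif(1, -0.5, 0.5)
  stopifnot(abs(z) <= 0.5)
  n <- state$n + dt / params$tau_n * (-state$n + params$nu * z)
  list(n = n, z = z)
}
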