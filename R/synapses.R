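#' Static Bernoulli synapse description
#'
#' A static synapse delivers a fixed-amplitude exponentially decaying
#' postsynaptic current after a conduction delay; each presynaptic spike is
#' transmitted independently with probability `p_release`.
#'
#' @param weight PSC amplitude (pA, signed: positive excitatory, negative
#'   inhibitory)
#' @param delay conduction delay (ms), must be positive
#' @param p_release per-spike transmission probability in \[0, 1\]
#' @return an object of class `static_synapse`
#' @export
static_synapse <- function(weight, delay = 1, p_release = 1) {
  if (delay <= 0) stop("delay must be positive")
  if (p_release < 0 || p_release > 1) stop("p_release must lie in [0, 1]")
  structure(list(weight = weight, delay = delay, p_release = p_release),
            class = "static_synapse")
}

#' Summed synaptic current state of one neuron
#'
#' Excitatory and inhibitory currents are kept as separate exponentially
#' decaying accumulators so that their kernels can differ; the total input to
#' the membrane is their sum. Default decay constants are fast AMPA/GABA-A
#' scale values (2 ms excitatory, 5 ms inhibitory).
#'
#' @param tau_syn_exc,tau_syn_inh kernel decay constants (ms)
#' @return an object of class `syn_current`
#' @export
syn_current <- function(tau_syn_exc = 2, tau_syn_inh = 5) {
  if (tau_syn_exc <= 0 || tau_syn_inh <= 0) stop("decay constants must be positive")
  structure(list(I_exc = 0, I_inh = 0,
                 tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh),
            class = "syn_current")
}

#' Decay synaptic currents over one step
#' @param state a `syn_current`
#' @param dt step (ms)
#' @return the decayed state
#' @export
decay_currents <- function(state, dt) {
  if (dt <= 0) stop("dt must be positive")
  state$I_exc <- state$I_exc * exp(-dt / state$tau_syn_exc)
  state$I_inh <- state$I_inh * exp(-dt / state$tau_syn_inh)
  state
}

#' Deliver one synaptic event
#'
#' Adds a signed PSC amplitude to the matching accumulator at spike-arrival
#' time (presynaptic spike time + delay). Simultaneous arrivals superpose
#' linearly.
#'
#' @param state a `syn_current`
#' @param weight signed amplitude (pA)
#' @return updated state
#' @export
deliver_spike <- function(state, weight) {
  if (weight >= 0) state$I_exc <- state$I_exc + weight
  else state$I_inh <- state$I_inh + weight
  state
}

#' Bernoulli release draw
#'
#' @param p_release transmission probability
#' @param n number of independent draws
#' @return logical vector: TRUE where the spike is transmitted
#' @export
bernoulli_release <- function(p_release, n = 1) {
  if (any(p_release < 0 | p_release > 1)) stop("p_release must lie in [0, 1]")
  stats::runif(n) < p_release
}

#' Tsodyks-Markram short-term plasticity parameters and state
#'
#' The phenomenological facilitation/depression model: a utilization variable
#' `u` (release probability analogue) is incremented towards 1 at each
#' presynaptic spike and relaxes back with `tau_facilitation`; a resource
#' variable `x` is depleted by each release and recovers with
#' `tau_depression`.
#'
#' Defaults follow the representative plasticity configuration
#' (`tau_facilitation` = 3158 ms, `tau_depression` = 527 ms, U = 0.5).
#'
#' @param U baseline utilization increment in \[0, 1\]
#' @param tau_facilitation facilitation time constant (ms, >= 0)
#' @param tau_depression depression time constant (ms, >= 0)
#' @return an object of class `tm_params`
#' @export
tm_params <- function(U = 0.5, tau_facilitation = 3158, tau_depression = 527) {
  if (U < 0 || U > 1) stop("U must lie in [0, 1]")
  if (tau_facilitation < 0 || tau_depression < 0) stop("time constants must be >= 0")
  structure(list(U = U, tau_facilitation = tau_facilitation,
                 tau_depression = tau_depression), class = "tm_params")
}

#' @rdname tm_params
#' @export
tm_state <- function() list(u = 0, x = 1, t_prev = -Inf)

#' Tsodyks-Markram update at a presynaptic spike
#'
#' Update order (stated explicitly because orderings differ across
#' simulators): with `dt = t_spike - t_prev`, first relax
#' `u <- u exp(-dt/tau_f)` and `x <- 1 - (1 - x) exp(-dt/tau_d)`; then
#' facilitate `u <- u + U (1 - u)`; the released fraction is `u x`; finally
#' deplete `x <- x (1 - u)`. The delivered amplitude is
#' `weight * u x / U`, normalized so the first spike from rest transmits the
#' nominal weight, which keeps plastic and static synapses comparable at
#' onset. Zero time constants recover the static synapse
#' (`weight_factor = U` on every spike).
#'
#' @param state a `tm_state` list
#' @param params a `tm_params` object
#' @param t_spike presynaptic spike time (ms); must exceed `state$t_prev`
#' @return list with updated `state` and `weight_factor = u x` (multiply the
#'   nominal weight by `weight_factor / U`)
#' @export
tm_on_presynaptic_spike <- function(state, params, t_spike) {
  if (t_spike <= state$t_prev) stop("presynaptic spike times must be increasing")
  dt <- t_spike - state$t_prev
  if (is.finite(dt)) {
    fd <- if (params$tau_facilitation > 0) exp(-dt / params$tau_facilitation) else 0
    dd <- if (params$tau_depression > 0) exp(-dt / params$tau_depression) else 0
    state$u <- state$u * fd
    state$x <- 1 - (1 - state$x) * dd
  }
  state$u <- state$u + params$U * (1 - state$u)
  weight_factor <- state$u * state$x
  state$x <- state$x * (1 - state$u)
  state$t_prev <- t_spike
  list(state = state, weight_factor = weight_factor)
}

#' Fixed point of the TM variables under periodic drive
#'
#' Closed-form steady state of the utilization/resource recursion for
#' presynaptic spikes at a fixed interval `T`:
#' `u* = U / (1 - (1 - U) exp(-T/tau_f))` and
#' `x* = (1 - exp(-T/tau_d)) / (1 - (1 - u*) exp(-T/tau_d))`, where `u*` is
#' the post-facilitation utilization and `x*` the pre-release resource level.
#'
#' @param params `tm_params`
#' @param interval inter-spike interval `T` (ms)
#' @return list with `u_star`, `x_star`, and their product `weight_factor`
#' @export
tm_fixed_point <- function(params, interval) {
  ef <- if (params$tau_facilitation > 0) exp(-interval / params$tau_facilitation) else 0
  ed <- if (params$tau_depression > 0) exp(-interval / params$tau_depression) else 0
  u_star <- params$U / (1 - (1 - params$U) * ef)
  x_star <- (1 - ed) / (1 - (1 - u_star) * ed)
  list(u_star = u_star, x_star = x_star, weight_factor = u_star * x_star)
}

#' Rebound pathway parameters
#'
#' Slow excitatory rebound paired with inhibitory input: every presynaptic
#' inhibitory spike additionally schedules, after `t_delay`, one excitatory
#' kernel of amplitude `w_rebound` decaying with `tau_rebound`. Release on
#' this pathway is non-probabilistic. Defaults are the experimentally
#' estimated values `t_delay = 14` ms and `tau_rebound = 10` ms; the
#' amplitude default is the calibrated exclusive-shell (model3) value.
#'
#' @param t_delay onset delay after the inhibitory arrival (ms, >= 0)
#' @param tau_rebound kernel decay constant (ms, > 0)
#' @param w_rebound excitatory amplitude (pA, >= 0)
#' @return an object of class `rebound_params`
#' @export
rebound_params <- function(t_delay = 14, tau_rebound = 10, w_rebound = 6) {
  if (t_delay < 0) stop("t_delay must be >= 0")
  if (tau_rebound <= 0) stop("tau_rebound must be positive")
  if (w_rebound < 0) stop("w_rebound must be >= 0")
  structure(list(t_delay = t_delay, tau_rebound = tau_rebound,
                 w_rebound = w_rebound), class = "rebound_params")
}

#' Rebound current at time t from a set of inhibitory arrivals
#'
#' `I(t) = sum_s w_rebound exp(-(t - t_s - t_delay)/tau_rebound)` over
#' arrivals `t_s` with `t >= t_s + t_delay`; zero before onset.
#'
#' @param arrival_times sorted inhibitory arrival times (ms)
#' @param params `rebound_params`
#' @param t evaluation time (ms)
#' @return current (pA)
#' @export
rebound_current <- function(arrival_times, params, t) {
  if (is.unsorted(arrival_times)) stop("arrival times must be sorted")
  onset <- arrival_times + params$t_delay
  active <- onset <= t
  if (!any(active)) return(0)
  sum(params$w_rebound * exp(-(t - onset[active]) / params$tau_rebound))
}
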