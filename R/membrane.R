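#' Membrane parameters for a leaky integrate-and-fire neuron
#'
#' Constructs the constant set describing one LIF neuron: leak dynamics,
#' spike threshold and reset, absolute refractoriness, and the rate of its
#' private background Poisson noise source.
#'
#' Defaults for the VMH populations come from slice electrophysiology of core
#' and shell neurons: core rests at -58.6 mV with threshold -43.1 mV and a
#' 40.3 ms membrane time constant; shell rests at -56.5 mV with threshold
#' -42 mV and a 41.6 ms time constant. Background noise runs at 5 Hz for core
#' and 10 Hz for shell neurons. Capacitance, reset and refractory period are
#' not constrained by those recordings and default to standard cortical-scale
#' values (200 pF, reset to rest, 2 ms).
#'
#' @param E_L resting potential (mV)
#' @param theta spike threshold (mV); must exceed `E_L`
#' @param tau_m membrane time constant (ms)
#' @param C_m membrane capacitance (pF)
#' @param V_reset post-spike potential (mV); defaults to `E_L`
#' @param t_ref absolute refractory period (ms)
#' @param noise_rate background Poisson input rate (Hz)
#' @return an object of class `membrane_params`
#' @seealso [core_membrane()], [shell_membrane()], [step_membrane()]
#' @export
membrane_params <- function(E_L, theta, tau_m, C_m = 200, V_reset = E_L,
                            t_ref = 2, noise_rate = 0) {
  stopifnot(is.numeric(E_L), is.numeric(theta), is.numeric(tau_m))
  if (theta <= E_L) stop("spike threshold must lie above the resting potential")
  if (tau_m <= 0) stop("tau_m must be positive")
  if (C_m <= 0) stop("C_m must be positive")
  if (t_ref < 0) stop("t_ref must be non-negative")
  if (V_reset > theta) stop("V_reset must not exceed the threshold")
  if (noise_rate < 0) stop("noise_rate must be non-negative")
  structure(list(E_L = E_L, theta = theta, tau_m = tau_m, C_m = C_m,
                 V_reset = V_reset, t_ref = t_ref, noise_rate = noise_rate),
            class = "membrane_params")
}

#' @rdname membrane_params
#' @param ... overrides passed to [membrane_params()]
#' @export
core_membrane <- function(...) {
  defaults <- list(E_L = -58.6, theta = -43.1, tau_m = 40.3, noise_rate = 5)
  do.call(membrane_params, utils::modifyList(defaults, list(...)))
}

#' @rdname membrane_params
#' @export
shell_membrane <- function(...) {
  defaults <- list(E_L = -56.5, theta = -42, tau_m = 41.6, noise_rate = 10)
  do.call(membrane_params, utils::modifyList(defaults, list(...)))
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf(
    "LIF membrane: E_L=%.1f mV, theta=%.1f mV, tau_m=%.1f ms, C_m=%.0f pF,\n  V_reset=%.1f mV, t_ref=%.1f ms, noise %.1f Hz\n",
    x$E_L, x$theta, x$tau_m, x$C_m, x$V_reset, x$t_ref, x$noise_rate))
  invisible(x)
}

#' Fresh neuron state at rest
#' @param params a `membrane_params` object
#' @return list with potential `V`, last spike time `t_last_spike` (NA before
#'   any spike) and refractory flag
#' @export
neuron_state <- function(params) {
  list(V = params$E_L, t_last_spike = NA_real_, in_refractory = FALSE)
}

#' Advance one membrane by one time step
#'
#' Exact exponential update of the leak equation for a current held constant
#' over the step:
#' `V' = E_L + (V - E_L) exp(-dt/tau_m) + I tau_m / C_m (1 - exp(-dt/tau_m))`.
#' Because the update is the closed-form solution for piecewise-constant
#' input, it carries no dt-dependent integration drift. While the neuron is
#' refractory the potential stays pinned at `V_reset`.
#'
#' @param state neuron state from [neuron_state()] or a previous step
#' @param I_total total input current over the step (pA)
#' @param params `membrane_params`
#' @param dt step length (ms); the engine uses 0.1 ms
#' @param t current time (ms), used to release the refractory pin
#' @return updated state
#' @export
step_membrane <- function(state, I_total, params, dt, t = NA_real_) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.finite(state$V) || !is.finite(I_total)) {
    stop(sprintf("non-finite membrane state at t=%s (V=%s, I=%s)",
                 format(t), format(state$V), format(I_total)))
  }
  if (state$in_refractory) {
    if (!is.na(t) && !is.na(state$t_last_spike) &&
        t - state$t_last_spike >= params$t_ref) {
      state$in_refractory <- FALSE
    } else {
      state$V <- params$V_reset
      return(state)
    }
  }
  decay <- exp(-dt / params$tau_m)
  state$V <- params$E_L + (state$V - params$E_L) * decay +
    I_total * params$tau_m / params$C_m * (1 - decay)
  state
}

#' Threshold crossing, spike emission and reset
#'
#' If the potential has reached threshold and the neuron is not refractory,
#' a spike is recorded at time `t`, the potential resets to `V_reset` and an
#' absolute refractory period of `t_ref` begins.
#'
#' @inheritParams step_membrane
#' @return list with the updated `state` and logical `spiked`
#' @export
detect_spike_and_reset <- function(state, params, t) {
  if (state$V >= params$theta && !state$in_refractory) {
    state$V <- params$V_reset
    state$t_last_spike <- t
    state$in_refractory <- params$t_ref > 0
    list(state = state, spiked = TRUE)
  } else {
    list(state = state, spiked = FALSE)
  }
}

#' Homogeneous Poisson background spike train
#'
#' Generates the private background noise train of one neuron: a homogeneous
#' Poisson process at `noise_rate`, delivered to the neuron as excitatory
#' events of weight `w_noise` (see [circuit_defaults()]).
#'
#' @param noise_rate rate (Hz)
#' @param duration train length (ms)
#' @param seed optional integer seed; when NULL the current RNG stream is used
#' @return numeric vector of strictly increasing spike times (ms)
#' @export
background_noise_train <- function(noise_rate, duration, seed = NULL) {
  if (noise_rate < 0) stop("noise_rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (noise_rate == 0 || duration <= 0) return(numeric(0))
  n <- stats::rpois(1, noise_rate * duration / 1000)
  sort(stats::runif(n, 0, duration))
}

#' Integrate one isolated neuron under a prescribed current
#'
#' Reference single-neuron integrator: applies the exact-exponential membrane
#' update and threshold/reset rule step by step under a user-supplied current
#' trace. Used for analytic protocols (relaxation, time-constant fits, ramp
#' rheobase) and as a slow, independent check on the network engine.
#'
#' @param params `membrane_params`
#' @param I numeric vector of input current per step (pA), or a single value
#'   recycled over `n_steps`
#' @param dt step (ms)
#' @param n_steps number of steps (defaults to `length(I)`)
#' @param V0 initial potential (mV), default `E_L`
#' @return list with vectors `t` (ms), `V` (mV, potential at the end of each
#'   step, before any reset applied at that step), `spikes` (spike times, ms)
#' @export
simulate_neuron <- function(params, I, dt = 0.1, n_steps = length(I),
                            V0 = params$E_L) {
  if (length(I) == 1) I <- rep(I, n_steps)
  stopifnot(length(I) == n_steps)
  decay <- exp(-dt / params$tau_m)
  gain <- params$tau_m / params$C_m * (1 - decay)
  V <- numeric(n_steps)
  spikes <- numeric(0)
  v <- V0
  ref_until <- -Inf
  for (k in seq_len(n_steps)) {
    t_k <- k * dt
    if (t_k <= ref_until) {
      v <- params$V_reset
    } else {
      v <- params$E_L + (v - params$E_L) * decay + I[k] * gain
    }
    V[k] <- v
    if (v >= params$theta && t_k > ref_until) {
      spikes <- c(spikes, t_k)
      ref_until <- t_k + params$t_ref
      v <- params$V_reset
    }
  }
  list(t = seq_len(n_steps) * dt, V = V, spikes = spikes)
}

#' Closed-form firing rate of a LIF neuron under constant current
#'
#' For suprathreshold constant input the inter-spike interval is
#' `t_ref + tau_m log((I R + E_L - V_reset) / (I R + E_L - theta))` with
#' `R = tau_m / C_m`; the rate is its reciprocal (returns 0 below rheobase).
#'
#' @param I constant current (pA)
#' @param params `membrane_params`
#' @return firing rate (Hz)
#' @export
lif_rate_closed_form <- function(I, params) {
  R <- params$tau_m / params$C_m
  v_inf <- params$E_L + I * R
  if (v_inf <= params$theta) return(0)
  isi <- params$t_ref + params$tau_m *
    log((v_inf - params$V_reset) / (v_inf - params$theta))
  1000 / isi
}
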