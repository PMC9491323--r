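# Hand-built miniature networks and an independent reference integrator used
# to validate the compiled engine.

# A feedforward chain: one input-receiving (amygdala) neuron driving one
# excitatory relay driving one target, all deterministic (p_release = 1, no
# noise), fixed delays.
chain_network <- function(w_input = 600, w1 = 700, w2 = 2000,
                          d1 = 1, d2 = 1.5) {
  pops <- data.frame(name = c("Amygdala", "Assessment", "Flight"),
                     size = c(1L, 1L, 1L),
                     sign = c("exc", "exc", "exc"),
                     offset = c(0L, 1L, 2L))
  quiet <- core_membrane(noise_rate = 0)
  membranes <- list(Amygdala = quiet, Assessment = quiet, Flight = quiet)
  edges <- data.frame(pre = c(1L, 2L), post = c(2L, 3L),
                      weight = c(w1, w2), delay = c(d1, d2),
                      p_release = 1, kind = "static", rebound = FALSE)
  cfg <- suppressWarnings(circuit_config("model1",
                                         constants = list(w_input = w_input)))
  structure(list(populations = pops, membranes = membranes,
                 neuron_pop = pops$name, n_neurons = 3L, edges = edges,
                 config = cfg, seed = 0L),
            class = "vmh_network")
}

# Brute-force reference integrator, written independently of the engine:
# vectors of per-neuron state advanced step by step in R with the same
# update order (decay currents -> deliver due events -> exact-exponential
# membrane update -> threshold/reset -> schedule downstream deliveries).
reference_chain_run <- function(input_times, net, duration_ms, dt = 0.1) {
  n <- net$n_neurons
  mem <- lapply(net$neuron_pop, function(nm) net$membranes[[nm]])
  n_steps <- round(duration_ms / dt)
  tau_e <- 2
  I <- numeric(n)
  V <- vapply(mem, function(m) m$E_L, 0)
  ref_until <- rep(-1, n)
  w_in <- net$config$constants$w_input
  # pending deliveries as a list keyed by step
  pending <- new.env()
  add_ev <- function(step, target, w) {
    key <- as.character(step)
    pending[[key]] <- rbind(pending[[key]], c(target, w))
  }
  for (t in input_times) add_ev(floor(t / dt), 1, w_in)
  spikes <- list()
  mean_factor <- tau_e / dt * (1 - exp(-dt / tau_e))
  for (k in 0:(n_steps - 1)) {
    I <- I * exp(-dt / tau_e)
    key <- as.character(k)
    if (!is.null(pending[[key]])) {
      for (r in seq_len(nrow(pending[[key]]))) {
        ev <- pending[[key]][r, ]
        I[ev[1]] <- I[ev[1]] + ev[2]
      }
      rm(list = key, envir = pending)
    }
    for (i in 1:n) {
      if (k <= ref_until[i]) { V[i] <- mem[[i]]$V_reset; next }
      a <- exp(-dt / mem[[i]]$tau_m)
      V[i] <- mem[[i]]$E_L + (V[i] - mem[[i]]$E_L) * a +
        I[i] * mean_factor * mem[[i]]$tau_m / mem[[i]]$C_m * (1 - a)
    }
    for (i in 1:n) {
      if (k <= ref_until[i]) next
      if (V[i] >= mem[[i]]$theta) {
        V[i] <- mem[[i]]$V_reset
        ref_until[i] <- k + round(mem[[i]]$t_ref / dt)
        spikes[[length(spikes) + 1]] <- c(i, (k + 1) * dt)
        out <- net$edges[net$edges$pre == i, , drop = FALSE]
        if (nrow(out)) {
          for (r in seq_len(nrow(out))) {
            add_ev(k + round(out$delay[r] / dt), out$post[r], out$weight[r])
          }
        }
      }
    }
  }
  m <- do.call(rbind, spikes)
  if (is.null(m)) data.frame(neuron_id = integer(0), time_ms = numeric(0))
  else data.frame(neuron_id = m[, 1], time_ms = m[, 2])
}

# a short deterministic schedule for engine tests
short_schedule <- function(len_s = 1) {
  session_schedule(n_trials = 1, trial_len = len_s, approach_len = len_s / 2,
                   iti = 0, buffer = 0)
}
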