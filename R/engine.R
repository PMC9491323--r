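#' Run a network simulation
#'
#' Clock-driven integration of a built circuit under the trial-structured
#' sensory drive. Per 0.1 ms step the engine decays synaptic currents,
#' delivers due events (sensory input, background noise, queued synaptic and
#' rebound events), advances every membrane with the exact-exponential
#' update, detects threshold crossings and enqueues downstream events at
#' spike time + delay, applying Bernoulli release and Tsodyks-Markram
#' factors per edge.
#'
#' All randomness derives from `seed`: four sub-seeds (input, noise, release,
#' spare) are drawn from it, so the same seed reproduces the run bit-exactly
#' and, e.g., the connectivity of a prebuilt network is unaffected by the
#' run seed.
#'
#' @param network a `vmh_network` from [build_circuit()]
#' @param schedule a `session_schedule`
#' @param profile a `rate_profile`
#' @param seed integer seed for input, noise and release randomness
#' @param dt integration step (ms)
#' @param input optional precomputed list of amygdala input spike trains
#'   (ms), one per amygdala neuron; generated from the schedule when NULL
#' @param shared_input share one sensory realization across amygdala neurons
#' @return an object of class `vmh_sim`: the spike record (data.frame with
#'   `neuron_id`, `population`, `time_ms`), the schedule/profile, and run
#'   metadata sufficient to regenerate it
#' @examples
#' net <- build_circuit(circuit_config("model1"), seed = 1)
#' sim <- run_simulation(net, session_schedule(n_trials = 1),
#'                       rate_profile(), seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(network, schedule = session_schedule(),
                           profile = rate_profile(), seed = 1, dt = 0.1,
                           input = NULL, shared_input = FALSE) {
  stopifnot(inherits(network, "vmh_network"))
  if (dt <= 0) stop("dt must be positive")
  sub <- derive_subseeds(seed)
  dur_ms <- session_duration(schedule) * 1000
  n_steps <- as.integer(round(dur_ms / dt))
  k <- network$config$constants

  amy <- population_ids(network, "Amygdala")
  if (is.null(input)) {
    input <- generate_input(schedule, profile, n_inputs = length(amy),
                            seed = sub["input"], shared = shared_input)
  }
  if (length(input) != length(amy)) {
    stop("need one input stream per amygdala neuron (", length(amy), ")")
  }

  # external events: sensory input onto amygdala + per-neuron background noise
  ext_t <- unlist(input, use.names = FALSE)
  ext_id <- rep(amy, vapply(input, length, 1L))
  ext_w <- rep(k$w_input, length(ext_t))

  set.seed(sub["noise"])
  for (p in seq_len(nrow(network$populations))) {
    nm <- network$populations$name[p]
    rate <- network$membranes[[nm]]$noise_rate
    if (rate <= 0) next
    pids <- population_ids(network, nm)
    counts <- stats::rpois(length(pids), rate * dur_ms / 1000)
    ext_t <- c(ext_t, stats::runif(sum(counts), 0, dur_ms))
    ext_id <- c(ext_id, rep(pids, counts))
    ext_w <- c(ext_w, rep(k$w_noise, sum(counts)))
  }
  ext_step <- as.integer(floor(ext_t / dt))
  keep <- ext_step < n_steps
  ord <- order(ext_step[keep], ext_id[keep])
  ext_step <- ext_step[keep][ord]
  ext_id <- ext_id[keep][ord]
  ext_w <- ext_w[keep][ord]

  mem <- do.call(rbind, lapply(network$neuron_pop, function(nm) {
    m <- network$membranes[[nm]]
    c(m$E_L, m$theta, m$tau_m, m$C_m, m$V_reset, m$t_ref)
  }))
  e <- network$edges
  tm <- network$config$tm
  reb <- network$config$rebound

  set.seed(sub["release"])
  out <- engine_run_cpp(
    network$n_neurons,
    mem[, 1], mem[, 2], mem[, 3], mem[, 4], mem[, 5],
    as.integer(round(mem[, 6] / dt)),
    2, 5,
    as.integer(e$pre - 1L), as.integer(e$post - 1L), e$weight,
    as.integer(round(e$delay / dt)), e$p_release, e$kind == "tm",
    e$rebound,
    tm$U, tm$tau_facilitation, tm$tau_depression,
    round(reb$t_delay / dt), reb$tau_rebound, reb$w_rebound,
    ext_step, as.integer(ext_id - 1L), ext_w,
    n_steps, dt)

  # spike times live on the 0.1 ms step grid; round away float accumulation
  spikes <- data.frame(neuron_id = out$neuron_id,
                       population = network$neuron_pop[out$neuron_id],
                       time_ms = round(out$time_ms, 1))
  new_vmh_sim(spikes, network, schedule, profile, dt, seed)
}

derive_subseeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4),
                  c("input", "noise", "release", "spare"))
}

new_vmh_sim <- function(spikes, network, schedule, profile, dt, seed) {
  pops <- network$populations
  meta <- list(variant = network$config$variant,
               r_input = network$config$r_input,
               r_feedback = network$config$r_feedback,
               dt = dt, seed = seed, network_seed = network$seed,
               package_version = as.character(utils::packageVersion("vmhswitch")))
  meta$config_hash <- config_hash(list(meta = meta, schedule = unclass(schedule),
                                       profile = unclass(profile),
                                       constants = network$config$constants))
  structure(list(spikes = spikes,
                 populations = stats::setNames(pops$size, pops$name),
                 schedule = schedule, profile = profile,
                 duration_ms = session_duration(schedule) * 1000,
                 meta = meta),
            class = "vmh_sim")
}

# FNV-1a hash of the canonical (deparsed) configuration
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.vmh_sim <- function(x, ...) {
  cat(sprintf("VMH simulation (%s): %.1f s, %d spikes, seed %d\n",
              x$meta$variant, x$duration_ms / 1000, nrow(x$spikes),
              x$meta$seed))
  invisible(x)
}

#' @export
summary.vmh_sim <- function(object, ...) {
  dur_s <- object$duration_ms / 1000
  counts <- table(factor(object$spikes$population, names(object$populations)))
  rates <- as.numeric(counts) / (dur_s * object$populations)
  out <- data.frame(population = names(object$populations),
                    n_neurons = as.integer(object$populations),
                    n_spikes = as.integer(counts),
                    rate_hz = round(rates, 3))
  cat(sprintf("VMH simulation (%s), %.1f s session, dt = %g ms, seed %d\n",
              object$meta$variant, dur_s, object$meta$dt, object$meta$seed))
  print(out, row.names = FALSE)
  invisible(out)
}

#' Raster and population-rate plot of a simulation
#'
#' Top panel: sensory input rate profile; middle: Assessment (red) and
#' Flight (blue) population PSTHs; bottom: spike raster by population.
#'
#' @param x a `vmh_sim`
#' @param bin PSTH bin (ms)
#' @param ... unused
#' @export
plot.vmh_sim <- function(x, bin = 20, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  tt <- seq(0, x$duration_ms / 1000, length.out = 2000)
  plot(tt, rate_at(tt, x$schedule, x$profile), type = "l",
       ylab = "input (Hz)", xlab = "")
  pa <- compute_psth(x, "Assessment", bin)
  pf <- compute_psth(x, "Flight", bin)
  plot(pa$mid / 1000, pa$rate, type = "l", col = "red",
       ylim = range(0, pa$rate, pf$rate), ylab = "rate (Hz/neuron)", xlab = "")
  graphics::lines(pf$mid / 1000, pf$rate, col = "blue")
  sp <- x$spikes
  plot(sp$time_ms / 1000, sp$neuron_id, pch = ".",
       col = as.integer(factor(sp$population)),
       ylab = "neuron", xlab = "time (s)")
  invisible(x)
}

#' Export and re-import a spike record
#'
#' Writes three plain-text files under `path` (created if needed):
#' `spikes.tsv` (neuron_id, population, time_ms), `populations.tsv`
#' (population, size), and `meta.yaml` (schedule, profile, run metadata).
#' `read_record()` reconstructs a `vmh_sim` that round-trips exactly.
#'
#' @param record a `vmh_sim`
#' @param path output directory
#' @return `export_record()` the paths written, invisibly; `read_record()` a
#'   `vmh_sim`
#' @export
export_record <- function(record, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f_sp <- file.path(path, "spikes.tsv")
  f_pop <- file.path(path, "populations.tsv")
  f_meta <- file.path(path, "meta.yaml")
  sp <- record$spikes
  sp$time_ms <- sprintf("%.1f", sp$time_ms)
  utils::write.table(sp, f_sp, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(population = names(record$populations),
               size = as.integer(record$populations)),
    f_pop, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(schedule = unclass(record$schedule),
                        profile = unclass(record$profile)[c("f_baseline", "f_max")],
                        duration_ms = record$duration_ms,
                        meta = record$meta), f_meta)
  invisible(c(f_sp, f_pop, f_meta))
}

#' @rdname export_record
#' @export
read_record <- function(path) {
  sp <- utils::read.table(file.path(path, "spikes.tsv"), header = TRUE,
                          sep = "\t", colClasses = c("integer", "character",
                                                     "numeric"))
  pop <- utils::read.table(file.path(path, "populations.tsv"), header = TRUE,
                           sep = "\t")
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  structure(list(spikes = sp,
                 populations = stats::setNames(as.integer(pop$size),
                                               pop$population),
                 schedule = do.call(session_schedule, meta$schedule),
                 profile = do.call(rate_profile, meta$profile),
                 duration_ms = meta$duration_ms,
                 meta = meta$meta),
            class = "vmh_sim")
}
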