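#' Load a simulation configuration file
#'
#' Reads a YAML configuration and returns a fully defaulted, validated
#' configuration. An empty file yields the package defaults (the printed
#' core/shell membrane values, the default trial schedule and rate profile,
#' Model 1). Unknown keys are rejected, and all schema violations are
#' reported together rather than at the first failure.
#'
#' Recognized blocks and keys:
#' \describe{
#'   \item{variant}{model1 | model2 | hybrid | model3 | model4}
#'   \item{r_input, r_feedback}{asymmetry ratios}
#'   \item{membrane}{`core:` / `shell:` with E_L, theta, tau_m, C_m,
#'     V_reset, t_ref, noise_rate}
#'   \item{tm}{U, tau_facilitation, tau_depression}
#'   \item{rebound}{t_delay, tau_rebound, w_rebound}
#'   \item{constants}{any [circuit_defaults()] entry}
#'   \item{schedule}{n_trials, trial_len, approach_len, iti, buffer}
#'   \item{stimulus}{f_baseline, f_max}
#'   \item{sim}{dt, seed}
#' }
#'
#' @param path YAML file path
#' @return list with elements `circuit` (a `circuit_config`), `schedule`,
#'   `profile`, and `sim` (list with `dt`, `seed`)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  errors <- character(0)
  known <- c("variant", "r_input", "r_feedback", "membrane", "tm", "rebound",
             "constants", "schedule", "stimulus", "sim")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    errors <- c(errors, paste0("unknown top-level key(s): ",
                               paste(bad, collapse = ", ")))
  }
  check_block <- function(block, allowed) {
    extra <- setdiff(names(raw[[block]] %||% list()), allowed)
    if (length(extra)) {
      errors <<- c(errors, paste0("unknown key(s) in '", block, "': ",
                                  paste(extra, collapse = ", ")))
    }
  }
  mem_keys <- c("E_L", "theta", "tau_m", "C_m", "V_reset", "t_ref",
                "noise_rate")
  check_block("tm", c("U", "tau_facilitation", "tau_depression"))
  check_block("rebound", c("t_delay", "tau_rebound", "w_rebound"))
  check_block("constants", names(circuit_defaults()))
  check_block("schedule", c("n_trials", "trial_len", "approach_len", "iti",
                            "buffer"))
  check_block("stimulus", c("f_baseline", "f_max"))
  check_block("sim", c("dt", "seed"))
  for (side in names(raw$membrane %||% list())) {
    if (!side %in% c("core", "shell")) {
      errors <- c(errors, paste0("unknown membrane block '", side, "'"))
    } else {
      extra <- setdiff(names(raw$membrane[[side]]), mem_keys)
      if (length(extra)) {
        errors <- c(errors, paste0("unknown key(s) in 'membrane.", side,
                                   "': ", paste(extra, collapse = ", ")))
      }
    }
  }
  if (length(errors)) {
    stop("invalid configuration (", path, "):\n  ",
         paste(errors, collapse = "\n  "))
  }
  core <- do.call(core_membrane, raw$membrane$core %||% list())
  shell <- do.call(shell_membrane, raw$membrane$shell %||% list())
  circuit <- circuit_config(
    variant = raw$variant %||% "model1",
    r_input = raw$r_input %||% 0.5,
    r_feedback = raw$r_feedback %||% 2.5,
    tm = do.call(tm_params, raw$tm %||% list()),
    rebound = do.call(rebound_params, raw$rebound %||% list()),
    constants = raw$constants %||% list(),
    core = core, shell = shell)
  list(circuit = circuit,
       schedule = do.call(session_schedule, raw$schedule %||% list()),
       profile = do.call(rate_profile, raw$stimulus %||% list()),
       sim = list(dt = raw$sim$dt %||% 0.1, seed = raw$sim$seed %||% 1L))
}

#' Write a configuration back to YAML
#'
#' `load_config(dump_config(cfg, f))` is semantically identical to `cfg`.
#'
#' @param config a list as returned by [load_config()]
#' @param path output file
#' @return `path`, invisibly
#' @export
dump_config <- function(config, path) {
  cc <- config$circuit
  out <- list(
    variant = cc$variant, r_input = cc$r_input, r_feedback = cc$r_feedback,
    membrane = list(core = unclass(cc$core), shell = unclass(cc$shell)),
    tm = unclass(cc$tm), rebound = unclass(cc$rebound),
    constants = cc$constants,
    schedule = unclass(config$schedule),
    stimulus = unclass(config$profile)[c("f_baseline", "f_max")],
    sim = config$sim)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, next to a set of output files, everything needed to regenerate
#' them: the full configuration echo, the seed, the package version and the
#' output inventory. Wall-clock time is informational only.
#'
#' @param dir output directory
#' @param config configuration list (as from [load_config()])
#' @param seed integer seed used
#' @param files character vector of files produced
#' @return path of the manifest, invisibly
#' @export
write_manifest <- function(dir, config, seed, files) {
  path <- file.path(dir, "manifest.yaml")
  cc <- config$circuit
  yaml::write_yaml(list(
    package = "vmhswitch",
    version = as.character(utils::packageVersion("vmhswitch")),
    seed = seed,
    config = list(variant = cc$variant, r_input = cc$r_input,
                  r_feedback = cc$r_feedback, tm = unclass(cc$tm),
                  rebound = unclass(cc$rebound), constants = cc$constants,
                  schedule = unclass(config$schedule),
                  stimulus = unclass(config$profile)[c("f_baseline", "f_max")],
                  sim = config$sim),
    outputs = basename(files),
    wallclock = format(Sys.time())), path)
  invisible(path)
}
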