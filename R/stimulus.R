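#' Trial schedule of a stimulation session
#'
#' A session is a buffer, `n_trials` trials separated by inter-trial
#' intervals, and a closing buffer. Each 20 s trial has a 10 s approach phase
#' (rising sensory drive) followed by a 10 s flight phase (falling drive).
#'
#' @param n_trials number of trials (default 10)
#' @param trial_len trial length (s)
#' @param approach_len length of the rising phase (s); must be < `trial_len`
#' @param iti inter-trial interval (s)
#' @param buffer baseline period at session start and end (s)
#' @return an object of class `session_schedule`
#' @export
session_schedule <- function(n_trials = 10, trial_len = 20, approach_len = 10,
                             iti = 6, buffer = 2) {
  stopifnot(n_trials >= 1)
  if (approach_len >= trial_len) stop("approach_len must be shorter than trial_len")
  if (any(c(trial_len, approach_len, iti, buffer) < 0)) {
    stop("durations must be non-negative")
  }
  structure(list(n_trials = as.integer(n_trials), trial_len = trial_len,
                 approach_len = approach_len, iti = iti, buffer = buffer),
            class = "session_schedule")
}

#' Total session duration in seconds
#'
#' `buffer + n_trials * trial_len + (n_trials - 1) * iti + buffer`; the
#' default 10-trial schedule lasts 258 s.
#'
#' @param schedule a `session_schedule`
#' @return duration (s)
#' @export
session_duration <- function(schedule) {
  2 * schedule$buffer + schedule$n_trials * schedule$trial_len +
    (schedule$n_trials - 1) * schedule$iti
}

#' Trial start times within a session
#' @param schedule a `session_schedule`
#' @return numeric vector of trial onset times (s)
#' @export
trial_starts <- function(schedule) {
  schedule$buffer +
    (seq_len(schedule$n_trials) - 1) * (schedule$trial_len + schedule$iti)
}

#' Sensory rate profile
#'
#' The drive to the amygdala population rises linearly during approach with
#' slope `a = f_max / 10` Hz/s, peaks at `f_max` at the approach/flight
#' boundary, then falls four times faster (a mouse flees faster than it
#' approaches), never dropping below `f_baseline`.
#'
#' @param f_baseline baseline rate (Hz, default 40)
#' @param f_max peak rate (Hz); the slope is `f_max / 10`
#' @return an object of class `rate_profile`
#' @export
rate_profile <- function(f_baseline = 40, f_max = 200) {
  if (f_baseline <= 0) stop("f_baseline must be positive")
  if (f_max < f_baseline) stop("f_max must be at least f_baseline")
  structure(list(f_baseline = f_baseline, f_max = f_max,
                 slope = f_max / 10), class = "rate_profile")
}

#' Sensory input rate at a session time
#'
#' Within a trial with local time `tau` (s):
#' `lambda = max(f_baseline, a tau)` during approach and
#' `lambda = max(f_baseline, f_max - 4 a (tau - t_approach))` during flight;
#' baseline in buffers and inter-trial intervals.
#'
#' @param t session time (s); vectorized
#' @param schedule a `session_schedule`
#' @param profile a `rate_profile`
#' @return rate (Hz) at each `t`
#' @export
rate_at <- function(t, schedule, profile) {
  dur <- session_duration(schedule)
  if (any(t < 0 | t > dur)) stop("t outside the session [0, ", dur, "] s")
  starts <- trial_starts(schedule)
  lambda <- rep(profile$f_baseline, length(t))
  a <- profile$slope
  for (s in starts) {
    tau <- t - s
    up <- tau > 0 & tau <= schedule$approach_len
    down <- tau > schedule$approach_len & tau < schedule$trial_len
    lambda[up] <- pmax(profile$f_baseline, a * tau[up])
    lambda[down] <- pmax(profile$f_baseline,
                         profile$f_max - 4 * a * (tau[down] - schedule$approach_len))
  }
  lambda
}

#' Generate the amygdala sensory input spike trains
#'
#' Draws one independent inhomogeneous Poisson realization of the session
#' rate profile per input stream (by default one stream per amygdala neuron)
#' using thinning against the peak rate. With `shared = TRUE` a single
#' realization is copied to every stream.
#'
#' @param schedule a `session_schedule`
#' @param profile a `rate_profile`
#' @param n_inputs number of streams (default 100)
#' @param seed optional integer seed
#' @param shared logical: share one realization across all streams
#' @return list of numeric vectors of spike times (ms), one per stream
#' @export
generate_input <- function(schedule, profile, n_inputs = 100, seed = NULL,
                           shared = FALSE) {
  stopifnot(n_inputs >= 1)
  if (!is.null(seed)) set.seed(seed)
  dur_ms <- session_duration(schedule) * 1000
  lambda_max <- max(profile$f_max, profile$f_baseline)
  one <- function() {
    n <- stats::rpois(1, lambda_max * dur_ms / 1000)
    cand <- sort(stats::runif(n, 0, dur_ms))
    if (!length(cand)) return(numeric(0))
    keep <- stats::runif(length(cand)) <
      rate_at(cand / 1000, schedule, profile) / lambda_max
    cand[keep]
  }
  if (shared) {
    tr <- one()
    replicate(n_inputs, tr, simplify = FALSE)
  } else {
    replicate(n_inputs, one(), simplify = FALSE)
  }
}
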