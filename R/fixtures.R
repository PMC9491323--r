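#' Synthetic spike records with known classification outcomes
#'
#' Construct deterministic (seeded) spike records that emulate the ideal
#' outcome categories without running any simulation, so the analysis stages
#' can be exercised and tested in isolation:
#' \describe{
#'   \item{ideal-switch}{Assessment ramps up gradually through the approach
#'     phase and collapses suddenly at a constructed onset; Flight jumps up
#'     at the onset, sustains, and decays gradually back to baseline before
#'     the trial ends. Meets all five Switch criteria.}
#'   \item{oscillating-reciprocal}{three alternating reciprocal bursts
#'     within each trial: repeated switch onsets with reversals, the
#'     Intermittent pattern.}
#'   \item{silent}{no spikes at all.}
#'   \item{baseline-only}{constant baseline firing in both populations, no
#'     structure.}
#' }
#' Spike trains are inhomogeneous Poisson realizations (thinning) of
#' piecewise-linear rate profiles, one independent stream per neuron, on the
#' 0.1 ms grid.
#'
#' The `onset_frac` parameter places the constructed switch within the
#' approach phase, which turns the ideal-switch fixture into a hard
#' sensory-threshold oracle: with `onset_frac = theta_in / f_max` the
#' switch occurs exactly when the input ramp crosses `theta_in`.
#'
#' @param kind fixture name
#' @param schedule a `session_schedule`
#' @param seed integer seed
#' @param n_per_pop neurons per population
#' @param r_base,r_peak baseline and peak rates (Hz per neuron)
#' @param onset_frac onset position within the approach phase (fraction)
#' @param profile `rate_profile` stored with the record (used by latency
#'   analyses)
#' @return a `vmh_sim` spike record (meta marks it as a fixture)
#' @export
make_fixture <- function(kind = c("ideal-switch", "oscillating-reciprocal",
                                  "silent", "baseline-only"),
                         schedule = session_schedule(n_trials = 1),
                         seed = 1, n_per_pop = 100, r_base = 1, r_peak = 30,
                         onset_frac = 0.8, profile = rate_profile()) {
  kind <- match.arg(kind)
  set.seed(seed)
  dur_ms <- session_duration(schedule) * 1000
  starts <- trial_starts(schedule) * 1000
  tl <- schedule$trial_len * 1000
  al <- schedule$approach_len * 1000

  # piecewise-linear rate profiles (Hz) per population as x/y knot vectors
  rate_fun <- function(knots_x, knots_y) {
    function(t) stats::approx(knots_x, knots_y, xout = t, rule = 2)$y
  }
  flat <- rate_fun(c(0, dur_ms), c(r_base, r_base))
  profiles <- switch(kind,
    "silent" = list(A = rate_fun(c(0, dur_ms), c(0, 0)),
                    F = rate_fun(c(0, dur_ms), c(0, 0))),
    "baseline-only" = list(A = flat, F = flat),
    "ideal-switch" = {
      onset <- onset_frac * al
      xa <- ya <- xf <- yf <- NULL
      for (s in starts) {
        # Assessment: gradual ramp to the onset, then an (effectively)
        # instantaneous collapse -- the hard-threshold idealization
        xa <- c(xa, s, s + onset, s + onset + 1, s + tl)
        ya <- c(ya, r_base, r_peak, 0.05 * r_peak, 0.05 * r_peak)
        # Flight: instantaneous jump at onset, sustain 4 s, gradual 4 s decay
        xf <- c(xf, s, s + onset, s + onset + 1, s + onset + 4000,
                s + onset + 8000, s + tl)
        yf <- c(yf, r_base, r_base, r_peak, r_peak, r_base, r_base)
      }
      list(A = rate_fun(c(0, xa, dur_ms), c(r_base, ya, 0.05 * r_peak)),
           F = rate_fun(c(0, xf, dur_ms), c(r_base, yf, r_base)))
    },
    "oscillating-reciprocal" = {
      xa <- ya <- xf <- yf <- NULL
      for (s in starts) {
        # Assessment active from trial start; three 2-s Flight bursts, each
        # suppressing Assessment (repeated reciprocal onsets with reversals)
        xa <- c(xa, s, s + 500); ya <- c(ya, r_base, r_peak)
        xf <- c(xf, s); yf <- c(yf, r_base)
        for (b in 0:2) {
          t0 <- s + 2000 + b * 4000
          xa <- c(xa, t0, t0 + 100, t0 + 2000, t0 + 2100)
          ya <- c(ya, r_peak, 0.05 * r_peak, 0.05 * r_peak, r_peak)
          xf <- c(xf, t0, t0 + 100, t0 + 2000, t0 + 2100)
          yf <- c(yf, r_base, r_peak, r_peak, r_base)
        }
        xa <- c(xa, s + tl); ya <- c(ya, r_base)
        xf <- c(xf, s + tl); yf <- c(yf, r_base)
      }
      list(A = rate_fun(c(0, xa, dur_ms), c(r_base, ya, r_base)),
           F = rate_fun(c(0, xf, dur_ms), c(r_base, yf, r_base)))
    })

  draw_pop <- function(f_rate, ids) {
    peak <- max(r_peak, r_base, 1)
    out <- lapply(ids, function(id) {
      n <- stats::rpois(1, peak * dur_ms / 1000)
      cand <- sort(stats::runif(n, 0, dur_ms))
      cand[stats::runif(length(cand)) < f_rate(cand) / peak]
    })
    data.frame(neuron_id = rep(ids, vapply(out, length, 1L)),
               time_ms = round(unlist(out), 1))
  }
  a <- draw_pop(profiles$A, seq_len(n_per_pop))
  f <- draw_pop(profiles$F, n_per_pop + seq_len(n_per_pop))
  a$population <- rep("Assessment", nrow(a))
  f$population <- rep("Flight", nrow(f))
  spikes <- rbind(a, f)
  spikes <- spikes[order(spikes$time_ms, spikes$neuron_id),
                   c("neuron_id", "population", "time_ms")]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes,
                 populations = c(Assessment = n_per_pop, Flight = n_per_pop),
                 schedule = schedule, profile = profile,
                 duration_ms = dur_ms,
                 meta = list(variant = paste0("fixture:", kind), seed = seed,
                             dt = 0.1,
                             config_hash = config_hash(list(kind, seed,
                                                            unclass(schedule))))),
            class = "vmh_sim")
}
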