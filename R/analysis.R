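#' Peri-stimulus time histogram of one population
#'
#' Raw-binned population rate: spike count per bin divided by bin width and
#' population size, giving Hz per neuron. Covers the full session. No
#' smoothing is applied — a smoothed PSTH would blur the "sudden" onset
#' criterion.
#'
#' @param record a `vmh_sim`
#' @param population population name present in the record
#' @param bin bin width (ms), default 20
#' @return an object of class `vmh_psth` with bin `edges`, midpoints `mid`
#'   (ms), per-bin `rate` (Hz per neuron), the population name and size
#' @export
compute_psth <- function(record, population, bin = 20) {
  if (!population %in% names(record$populations)) {
    stop("unknown population: ", population)
  }
  n_pop <- record$populations[[population]]
  edges <- seq(0, record$duration_ms + bin, by = bin)
  t <- record$spikes$time_ms[record$spikes$population == population]
  counts <- if (length(t)) {
    tabulate(findInterval(t, edges, left.open = TRUE), length(edges) - 1)
  } else rep(0L, length(edges) - 1)
  structure(list(edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
                 rate = counts / (bin / 1000) / n_pop,
                 population = population, n_pop = n_pop, bin = bin),
            class = "vmh_psth")
}

#' @export
print.vmh_psth <- function(x, ...) {
  cat(sprintf("PSTH of %s (%d neurons): %d bins of %g ms, mean %.2f Hz/neuron\n",
              x$population, x$n_pop, length(x$rate), x$bin, mean(x$rate)))
  invisible(x)
}

psth_window <- function(psth, from_ms, to_ms) {
  sel <- psth$mid >= from_ms & psth$mid < to_ms
  list(mid = psth$mid[sel], rate = psth$rate[sel])
}

#' Detect the switch onset within a trial
#'
#' The onset is the first bin in the trial window where the Flight rate
#' exceeds the Assessment rate by more than 25% of the larger of the two
#' PSTHs' maxima over that window. The rule is scale-covariant: rescaling
#' both PSTHs by a common factor leaves the onset unchanged.
#'
#' @param psth_A,psth_F Assessment and Flight `vmh_psth` with identical
#'   binning
#' @param window `c(from, to)` in ms (one trial)
#' @param frac threshold fraction of the joint PSTH maximum (default 0.25)
#' @return onset time (ms, bin midpoint) or `NA` if no crossing
#' @export
detect_switch_onset <- function(psth_A, psth_F, window, frac = 0.25) {
  check_same_bins(psth_A, psth_F)
  a <- psth_window(psth_A, window[1], window[2])
  f <- psth_window(psth_F, window[1], window[2])
  m <- max(a$rate, f$rate)
  if (m <= 0) return(NA_real_)
  hit <- which(f$rate - a$rate > frac * m)
  if (!length(hit)) NA_real_ else a$mid[hit[1]]
}

check_same_bins <- function(p1, p2) {
  if (length(p1$edges) != length(p2$edges) ||
      any(p1$edges != p2$edges)) stop("PSTHs must share bin edges")
}

#' Operationalization constants for trial classification
#'
#' The qualitative Switch criteria are made testable with explicit
#' constants: a "gradual" onset takes at least `T_gradual` between the 10%
#' and 90% levels of its transition span, a "sudden" one at most `T_sudden`;
#' Flight's post-switch decay counts as gradual when it takes at least
#' `T_gradual_fall` (smaller than `T_gradual` because the flight-phase input
#' ramp falls four times faster than the approach ramp rises, so even a
#' decay that tracks the input lasts only a few times `T_sudden`).
#' Reciprocity is checked within `W_recip` after onset; sustained Flight
#' firing must last at least `D_sustain`; the baseline band is the
#' inter-trial-interval mean rate plus `k_sd` standard deviations of the
#' binned baseline rate. Sudden-transition times are measured on the raw
#' PSTH with persistence-based level crossings (a level counts as crossed
#' only when it holds for `persist_bins` consecutive bins), which rejects
#' single-bin noise without the time bias a moving average would add;
#' gradual envelopes are measured on a `smooth_slow_bins` moving average
#' (about 1 s).
#'
#' @param T_gradual minimum 10-90% rise time to count as gradual (s)
#' @param T_sudden maximum 10-90% transition time to count as sudden (s)
#' @param T_gradual_fall minimum 90-10% Flight decay time to count as
#'   gradual (s)
#' @param W_recip window after onset for the reciprocity check (s)
#' @param D_sustain minimum sustained Flight activity (s)
#' @param k_sd width of the baseline band in SDs
#' @param recip_frac Assessment must fall to this fraction of its trial
#'   maximum after Flight onset (default 0.4)
#' @param persist_bins consecutive bins required for a level crossing
#' @param smooth_slow_bins moving-average width (bins) for gradual
#'   envelope measurements
#' @return named list of constants
#' @export
classification_constants <- function(T_gradual = 2, T_sudden = 0.5,
                                     T_gradual_fall = 0.6,
                                     W_recip = 1, D_sustain = 1, k_sd = 2,
                                     recip_frac = 0.4,
                                     persist_bins = 3,
                                     smooth_slow_bins = 51) {
  list(T_gradual = T_gradual, T_sudden = T_sudden,
       T_gradual_fall = T_gradual_fall, W_recip = W_recip,
       D_sustain = D_sustain, k_sd = k_sd, recip_frac = recip_frac,
       persist_bins = persist_bins, smooth_slow_bins = smooth_slow_bins)
}

# centered moving average with partial windows at the boundaries
moving_avg <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# persistence-based level crossings: an index qualifies only when the
# condition holds for `p` consecutive bins starting there (forward) or
# ending there (backward)
persistent_idx <- function(cond, p) {
  if (p <= 1) return(which(cond))
  runs <- rle(cond)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values & runs$lengths >= p)
  unlist(lapply(ok, function(i) starts[i]:(ends[i] - p + 1)))
}

# first time x crosses upward through 10% and then 90% of the span
# [lo_level, hi_level]; returns the 10-90% rise time in seconds, NA if the
# trace never completes the transition inside the window
rise_time <- function(mid, x, lo_level, hi_level, from, to, persist = 1) {
  if (is.na(lo_level) || is.na(hi_level)) return(NA_real_)
  sel <- which(mid >= from & mid <= to)
  if (!length(sel) || hi_level <= lo_level) return(NA_real_)
  span <- hi_level - lo_level
  xs <- x[sel]
  i90 <- persistent_idx(xs >= lo_level + 0.9 * span, persist)
  if (!length(i90)) return(NA_real_)
  i90 <- i90[1]
  i10 <- persistent_idx(xs <= lo_level + 0.1 * span, persist)
  i10 <- i10[i10 <= i90]
  if (!length(i10)) return(0)
  (mid[sel[i90]] - mid[sel[max(i10)]]) / 1000
}

# 90-10% fall time across the span [hi_level -> lo_level], searching
# forward from `from`: first bin at or below the 10% level, back to the
# last preceding bin at or above the 90% level
fall_time <- function(mid, x, hi_level, lo_level, from, to, persist = 1) {
  if (is.na(lo_level) || is.na(hi_level)) return(NA_real_)
  sel <- which(mid >= from & mid <= to)
  if (!length(sel) || hi_level <= lo_level) return(NA_real_)
  span <- hi_level - lo_level
  xs <- x[sel]
  i10 <- persistent_idx(xs <= lo_level + 0.1 * span, persist)
  if (!length(i10)) return(NA_real_)
  i10 <- i10[1]
  i90 <- persistent_idx(xs >= lo_level + 0.9 * span, persist)
  i90 <- i90[i90 <= i10]
  if (!length(i90)) return(NA_real_)
  (mid[sel[i10]] - mid[sel[max(i90)]]) / 1000
}

window_mean <- function(mid, x, from, to) {
  sel <- mid >= from & mid <= to
  if (!any(sel)) NA_real_ else mean(x[sel])
}

# Baseline mean and SD of the binned rate outside trials (buffers + ITIs)
baseline_stats <- function(psth, schedule) {
  starts <- trial_starts(schedule) * 1000
  in_trial <- rep(FALSE, length(psth$mid))
  for (s in starts) {
    in_trial <- in_trial |
      (psth$mid >= s & psth$mid < s + schedule$trial_len * 1000)
  }
  r <- psth$rate[!in_trial]
  list(mean = mean(r), sd = stats::sd(r))
}

#' Classify one trial as Switch, Intermittent or None
#'
#' A trial is a Switch when all five criteria hold: (1) Assessment onset is
#' gradual and its decrease sudden; (2) Flight onset is sudden and its
#' decrease gradual; (3) firing is reciprocal — within `W_recip` of the
#' switch onset the Assessment rate falls to at most 40% of its trial
#' maximum; (4) Flight activity is sustained at least `D_sustain` but
#' returns to the baseline band before the trial ends; (5) Assessment does
#' not rise beyond the baseline band after Flight firing stops. A non-Switch
#' trial with at least two reciprocal onset events separated by a reversal
#' is Intermittent; anything else is None.
#'
#' @param psth_A,psth_F population PSTHs with shared bins
#' @param schedule the `session_schedule` (trial geometry and baseline
#'   periods)
#' @param trial trial index (1-based)
#' @param constants see [classification_constants()]
#' @param profile optional `rate_profile`; when given, the sensory input
#'   rate at the detected onset is reported
#' @return an object of class `vmh_classification`: `label`, logical
#'   `criteria` (length 5), `onset_ms`, `latency_s`, `input_rate_at_onset`,
#'   `n_onset_events`
#' @export
classify_trial <- function(psth_A, psth_F, schedule, trial = 1,
                           constants = classification_constants(),
                           profile = NULL) {
  check_same_bins(psth_A, psth_F)
  t0 <- trial_starts(schedule)[trial] * 1000
  t1 <- t0 + schedule$trial_len * 1000
  a <- psth_window(psth_A, t0, t1)
  f <- psth_window(psth_F, t0, t1)
  base_A <- baseline_stats(psth_A, schedule)
  base_F <- baseline_stats(psth_F, schedule)
  k <- constants
  crit <- rep(FALSE, 5)
  meas <- list(rise_A = NA_real_, fall_A = NA_real_, rise_F = NA_real_,
               fall_F = NA_real_)

  onset <- detect_switch_onset(psth_A, psth_F, c(t0, t1))
  n_events <- count_onset_events(a$rate, f$rate)

  # baseline-subtracted traces: raw for sudden transitions (crossings use
  # persistence instead of smoothing), wide moving average for gradual
  # envelopes
  a_raw <- pmax(a$rate - base_A$mean, 0)
  f_raw <- pmax(f$rate - base_F$mean, 0)
  a_slow <- moving_avg(a_raw, k$smooth_slow_bins)
  f_slow <- moving_avg(f_raw, k$smooth_slow_bins)

  if (!is.na(onset)) {
    # levels flanking the switch (skipping the transition bins)
    pre_A <- window_mean(a$mid, a_raw, onset - 1200, onset - 200)
    post_A <- window_mean(a$mid, a_raw, onset + 500, onset + 1500)
    pre_F <- window_mean(f$mid, f_raw, onset - 1200, onset - 200)
    post_F <- window_mean(f$mid, f_raw, onset + 500, onset + 1500)

    # (1) Assessment: gradual onset (10-90% of its pre-switch envelope),
    #     sudden decrease across the switch
    peak_A <- max(a_slow[a$mid <= onset + 500])
    rise_A <- rise_time(a$mid, a_slow, 0, peak_A, t0, onset + 500)
    fall_A <- fall_time(a$mid, a_raw, pre_A, post_A,
                        onset - 1000, onset + 2500, k$persist_bins)
    crit[1] <- !is.na(rise_A) && rise_A >= k$T_gradual &&
      !is.na(fall_A) && fall_A <= k$T_sudden
    # (2) Flight: sudden onset across the switch, gradual decrease back to
    #     baseline afterwards
    rise_F <- rise_time(f$mid, f_raw, pre_F, post_F,
                        onset - 1000, onset + 2500, k$persist_bins)
    peak_F <- max(f_slow[f$mid >= onset])
    fall_F <- fall_time(f$mid, f_slow, peak_F, 0, onset, t1)
    crit[2] <- !is.na(rise_F) && rise_F <= k$T_sudden &&
      !is.na(fall_F) && fall_F >= k$T_gradual_fall
    meas <- list(rise_A = rise_A, fall_A = fall_A, rise_F = rise_F,
                 fall_F = fall_F)
    # (3) reciprocity: Assessment collapses to <= 40% of its trial max
    win <- a$mid >= onset & a$mid <= onset + k$W_recip * 1000
    crit[3] <- any(win) && min(a$rate[win]) <= k$recip_frac * max(a$rate)
  }
  # (4) Flight sustained, then back to baseline within the trial
  band_F <- base_F$mean + k$k_sd * base_F$sd
  active <- moving_avg(f_raw, 5) + base_F$mean > band_F
  runs <- rle(active)
  bin_s <- psth_F$bin / 1000
  long_run <- any(runs$lengths[runs$values] * bin_s >= k$D_sustain)
  tail_bins <- f$mid > t1 - 1000
  returned <- mean(f$rate[tail_bins]) <= band_F
  crit[4] <- long_run && returned
  # (5) Assessment stays at baseline after Flight stops
  if (long_run) {
    ends <- cumsum(runs$lengths)
    last_active <- max(ends[runs$values])
    post <- seq_along(a$rate) > last_active
    crit[5] <- !any(post) ||
      mean(a$rate[post]) <= base_A$mean + k$k_sd * base_A$sd
  }

  # reciprocal events only count when Flight shows real activity (smoothed
  # rate at least double its baseline and outside the noise band): pure
  # baseline noise must not register as intermittent firing
  f_sm <- moving_avg(f$rate, k$smooth_slow_bins)
  if (max(f_sm) <= 2 * base_F$mean + k$k_sd * base_F$sd) n_events <- 0L
  label <- if (all(crit)) "Switch"
           else if (n_events >= 2) "Intermittent"
           else "None"
  # latency runs from the start of the increase in sensory input: the ramp
  # a*tau exceeds the baseline floor only after f_baseline / slope seconds
  ramp_delay_s <- if (!is.null(profile)) {
    profile$f_baseline / profile$slope
  } else 0
  latency <- if (!is.na(onset)) (onset - t0) / 1000 - ramp_delay_s
             else NA_real_
  structure(list(label = label, criteria = crit, onset_ms = onset,
                 latency_s = latency,
                 input_rate_at_onset = if (!is.na(onset) && !is.null(profile))
                   rate_at(onset / 1000, schedule, profile) else NA_real_,
                 n_onset_events = n_events, measures = meas, trial = trial),
            class = "vmh_classification")
}

# number of reciprocal onset events: maximal runs of "Flight exceeds
# Assessment by > 25% of the joint maximum", counted only when separated by
# a reversal (Flight back below Assessment)
count_onset_events <- function(rate_A, rate_F, frac = 0.25) {
  m <- max(rate_A, rate_F)
  if (m <= 0) return(0L)
  above <- rate_F - rate_A > frac * m
  reversed <- rate_F < rate_A
  n <- 0L; armed <- TRUE
  for (i in seq_along(above)) {
    if (above[i] && armed) { n <- n + 1L; armed <- FALSE }
    else if (reversed[i]) armed <- TRUE
  }
  n
}

#' @export
print.vmh_classification <- function(x, ...) {
  cat(sprintf("trial %d: %s  [criteria %s]", x$trial, x$label,
              paste(ifelse(x$criteria, "+", "-"), collapse = "")))
  if (!is.na(x$onset_ms)) {
    cat(sprintf("  onset %.2f s, latency %.2f s", x$onset_ms / 1000,
                x$latency_s))
  }
  cat("\n")
  invisible(x)
}

#' Classify every trial of a run
#'
#' Applies [classify_trial()] per trial and aggregates: a run is a Switch
#' when at least `switch_frac` of trials classify Switch; otherwise it is
#' Intermittent when at least two trials are Intermittent or switching is
#' inconsistent (at least two, but too few, Switch trials); otherwise None.
#'
#' @param record a `vmh_sim`
#' @param bin PSTH bin (ms)
#' @param constants see [classification_constants()]
#' @param switch_frac fraction of Switch trials required (default 0.8)
#' @return an object of class `vmh_run_classification`: run `label`,
#'   per-trial list `trials`, and the label table
#' @export
classify_run <- function(record, bin = 20,
                         constants = classification_constants(),
                         switch_frac = 0.8) {
  pa <- compute_psth(record, "Assessment", bin)
  pf <- compute_psth(record, "Flight", bin)
  trials <- lapply(seq_len(record$schedule$n_trials), function(i) {
    classify_trial(pa, pf, record$schedule, i, constants, record$profile)
  })
  labels <- vapply(trials, function(x) x$label, "")
  n_sw <- sum(labels == "Switch")
  label <- if (n_sw >= switch_frac * length(labels)) "Switch"
           else if (sum(labels == "Intermittent") >= 2 || n_sw >= 2) "Intermittent"
           else "None"
  structure(list(label = label, trials = trials, labels = labels),
            class = "vmh_run_classification")
}

#' @export
print.vmh_run_classification <- function(x, ...) {
  cat(sprintf("run: %s  (%s)\n", x$label,
              paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Switch-triggered average of normalized PSTHs
#'
#' For every trial with a detected onset, a 20-s window of each population
#' PSTH centered on the onset is cut out, divided by its own maximum, and
#' the windows are averaged bin-wise. Set `neuron_id` to repeat the
#' procedure on a single neuron's PSTH.
#'
#' @param record a `vmh_sim`
#' @param bin PSTH bin (ms)
#' @param window_s window length centered on the onset (s)
#' @param neuron_id optional single neuron id for the single-neuron variant
#' @return list with `lag_ms`, matrices averaged into `assessment` and
#'   `flight` (NA-filled and flagged `empty = TRUE` when no trial has an
#'   onset), and the per-trial `onsets_ms`
#' @export
switch_triggered_average <- function(record, bin = 20, window_s = 20,
                                     neuron_id = NULL) {
  pa <- compute_psth(record, "Assessment", bin)
  pf <- compute_psth(record, "Flight", bin)
  schedule <- record$schedule
  onsets <- vapply(seq_len(schedule$n_trials), function(i) {
    t0 <- trial_starts(schedule)[i] * 1000
    detect_switch_onset(pa, pf, c(t0, t0 + schedule$trial_len * 1000))
  }, 0)
  onsets <- onsets[!is.na(onsets)]
  half <- window_s * 1000 / 2
  # lags are whole bins so that onset + lag lands on bin midpoints
  lag <- seq(-half, half - bin, by = bin)
  if (!length(onsets)) {
    return(list(lag_ms = lag, assessment = rep(NA_real_, length(lag)),
                flight = rep(NA_real_, length(lag)), onsets_ms = numeric(0),
                empty = TRUE))
  }
  cut_norm <- function(psth, onset) {
    r <- stats::approx(psth$mid, psth$rate, xout = onset + lag, rule = 2)$y
    m <- max(r)
    if (m > 0) r / m else r
  }
  if (!is.null(neuron_id)) {
    # single-neuron variant: same windows and normalization, rate of one cell
    one <- record
    one$spikes <- one$spikes[one$spikes$neuron_id == neuron_id, , drop = FALSE]
    pop <- record$spikes$population[record$spikes$neuron_id == neuron_id][1]
    one$populations <- stats::setNames(1L, pop)
    pn <- compute_psth(one, pop, bin)
    n_mat <- vapply(onsets, function(o) cut_norm(pn, o), lag)
    return(list(lag_ms = lag, neuron = rowMeans(n_mat),
                onsets_ms = onsets, empty = FALSE))
  }
  a_mat <- vapply(onsets, function(o) cut_norm(pa, o), lag)
  f_mat <- vapply(onsets, function(o) cut_norm(pf, o), lag)
  list(lag_ms = lag, assessment = rowMeans(a_mat), flight = rowMeans(f_mat),
       onsets_ms = onsets, empty = FALSE)
}

#' Latency-versus-slope thresholding analysis
#'
#' For runs at different sensory input slopes, collects per trial the
#' latency from the start of the increase in sensory input (the moment the
#' approach ramp exceeds the baseline floor) to the switch onset, and the
#' input rate at onset. Sensory thresholding predicts an inverse
#' latency-slope relation (switches happen at a fixed input level, which a
#' steeper ramp reaches sooner) and a low dispersion of the input rate at
#' onset across slopes.
#'
#' @param records list of `vmh_sim` runs, each with its own `rate_profile`
#' @param bin PSTH bin (ms)
#' @return an object of class `vmh_latency`: per-trial data.frame
#'   (`slope`, `trial`, `latency_s`, `input_rate_at_onset`), Spearman
#'   `rho` of latency vs. slope, its p-value, the coefficient of variation
#'   `input_rate_cv`, and `insufficient` when fewer than 3 slopes yielded
#'   switches
#' @export
latency_analysis <- function(records, bin = 20) {
  rows <- do.call(rbind, lapply(records, function(rec) {
    pa <- compute_psth(rec, "Assessment", bin)
    pf <- compute_psth(rec, "Flight", bin)
    sched <- rec$schedule
    do.call(rbind, lapply(seq_len(sched$n_trials), function(i) {
      t0 <- trial_starts(sched)[i] * 1000
      onset <- detect_switch_onset(pa, pf,
                                   c(t0, t0 + sched$trial_len * 1000))
      if (is.na(onset)) return(NULL)
      latency <- (onset - t0) / 1000 -
        rec$profile$f_baseline / rec$profile$slope
      data.frame(slope = rec$profile$slope, trial = i, latency_s = latency,
                 input_rate_at_onset = rate_at(onset / 1000, sched,
                                               rec$profile))
    }))
  }))
  n_slopes <- length(unique(rows$slope))
  insufficient <- is.null(rows) || n_slopes < 3
  rho <- p <- NA_real_
  cv <- NA_real_
  if (!insufficient) {
    ct <- suppressWarnings(stats::cor.test(rows$latency_s, rows$slope,
                                           method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
    cv <- stats::sd(rows$input_rate_at_onset) / mean(rows$input_rate_at_onset)
  }
  structure(list(table = rows, rho = rho, p_value = p, input_rate_cv = cv,
                 n_slopes = n_slopes, insufficient = insufficient),
            class = "vmh_latency")
}

#' @export
print.vmh_latency <- function(x, ...) {
  if (x$insufficient) {
    cat("latency analysis: insufficient (need switches at >= 3 slopes)\n")
  } else {
    cat(sprintf(
      "latency vs slope over %d slopes: Spearman rho = %.3f (p = %.2g);\n  input rate at onset CV = %.3f\n",
      x$n_slopes, x$rho, x$p_value, x$input_rate_cv))
  }
  invisible(x)
}

#' Parameter sweep with per-point classification
#'
#' Runs one single-trial simulation per grid point per seed and records the
#' run classification. Failures at single points are recorded as failed
#' rows and the sweep continues.
#'
#' @param variant model variant name
#' @param grid data.frame whose columns are `circuit_config()` /
#'   `tm_params()` / `rebound_params()` parameter names (`r_input`,
#'   `r_feedback`, `tau_facilitation`, `tau_depression`, `t_delay`,
#'   `tau_rebound`)
#' @param seeds integer vector of run seeds
#' @param schedule session per point (default: one trial)
#' @param profile `rate_profile`
#' @param constants circuit constant overrides (see [circuit_defaults()])
#' @return an object of class `vmh_sweep`: the grid with one row per
#'   point x seed, columns `label` and `ok`
#' @export
run_sweep <- function(variant, grid, seeds = 1,
                      schedule = session_schedule(n_trials = 1),
                      profile = rate_profile(), constants = list()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  rows <- expand.grid(point = seq_len(nrow(grid)), seed = seeds)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    pt <- grid[rows$point[i], , drop = FALSE]
    seed <- rows$seed[i]
    out <- tryCatch({
      cfg <- sweep_point_config(variant, pt, constants)
      net <- build_circuit(cfg, seed = seed)
      sim <- run_simulation(net, schedule, profile, seed = seed)
      classify_run(sim)$label
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    cbind(pt, data.frame(seed = seed, label = out,
                         ok = !startsWith(out, "failed"), row.names = NULL))
  })
  structure(list(table = do.call(rbind, res), variant = variant),
            class = "vmh_sweep")
}

sweep_point_config <- function(variant, pt, constants = list()) {
  pt <- as.list(pt)
  tm <- tm_params(tau_facilitation = pt$tau_facilitation %||% 1000,
                  tau_depression = pt$tau_depression %||% 200)
  reb <- if (!is.null(pt$tau_rebound) || !is.null(pt$t_delay)) {
    rebound_params(t_delay = pt$t_delay %||% 14,
                   tau_rebound = pt$tau_rebound %||% 10)
  } else rebound_params()
  circuit_config(variant, r_input = pt$r_input %||% 0.5,
                 r_feedback = pt$r_feedback %||% 2.5,
                 tm = tm, rebound = reb, constants = constants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vmh_sweep <- function(x, ...) {
  cat(sprintf("sweep of %s: %d rows\n", x$variant, nrow(x$table)))
  print(table(x$table$label))
  invisible(x)
}

#' Project a sweep's parameter space to three dimensions
#'
#' For parameter spaces of more than three dimensions the z-scored parameter
#' matrix is reduced to its top three principal components; spaces of three
#' or fewer dimensions pass through unchanged (with a note).
#'
#' @param sweep a `vmh_sweep` or its table
#' @param param_cols parameter column names (default: all numeric columns
#'   except `seed`)
#' @return list with `coords` (n x <=3 matrix), `loadings`,
#'   `explained_variance`, `labels`, and `passthrough`
#' @export
pca_project <- function(sweep, param_cols = NULL) {
  tab <- if (inherits(sweep, "vmh_sweep")) sweep$table else sweep
  if (is.null(param_cols)) {
    param_cols <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)], "seed")
  }
  x <- as.matrix(tab[, param_cols, drop = FALSE])
  if (length(param_cols) <= 3) {
    return(list(coords = x, loadings = diag(ncol(x)),
                explained_variance = rep(NA_real_, ncol(x)),
                labels = tab$label, passthrough = TRUE,
                note = "3 or fewer parameter dimensions: identity pass-through"))
  }
  sds <- apply(x, 2, stats::sd)
  z <- scale(x, scale = ifelse(sds > 0, sds, 1))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  keep <- seq_len(min(3, ncol(pc$x)))
  list(coords = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[keep],
       labels = tab$label, passthrough = FALSE)
}
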