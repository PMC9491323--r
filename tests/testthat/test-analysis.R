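# build a bare spike record without simulating
bare_record <- function(spikes, n_per_pop = 100, schedule = session_schedule(1)) {
  structure(list(spikes = spikes,
                 populations = c(Assessment = n_per_pop, Flight = n_per_pop),
                 schedule = schedule, profile = rate_profile(),
                 duration_ms = session_duration(schedule) * 1000,
                 meta = list(variant = "test", seed = 0, dt = 0.1)),
            class = "vmh_sim")
}

# synthetic PSTH with prescribed rates
bare_psth <- function(rate, bin = 20, n_pop = 100) {
  edges <- seq(0, length(rate) * bin, by = bin)
  structure(list(edges = edges, mid = edges[-1] - bin / 2, rate = rate,
                 population = "x", n_pop = n_pop, bin = bin),
            class = "vmh_psth")
}

test_that("PSTH counts, normalization and conservation are exact", {
  # 100 neurons firing once each inside one 20 ms bin -> 50 Hz per neuron
  sp <- data.frame(neuron_id = 1:100, population = "Assessment",
                   time_ms = seq(100.1, 119.9, length.out = 100))
  rec <- bare_record(sp)
  p <- compute_psth(rec, "Assessment")
  expect_equal(max(p$rate), 50)
  expect_equal(sum(p$rate > 0), 1)
  # integral equals the raw spike count
  expect_equal(sum(p$rate * p$bin / 1000 * p$n_pop), 100)
  # empty population -> all-zero PSTH; unknown population -> error
  expect_true(all(compute_psth(rec, "Flight")$rate == 0))
  expect_error(compute_psth(rec, "Shell"), "unknown population")
})

test_that("switch onset detection applies the 25% rule and is scale-covariant", {
  # step PSTHs: A drops 10 -> 0 and F jumps 0 -> 10 at bin 51
  a <- bare_psth(c(rep(10, 50), rep(0, 50)))
  f <- bare_psth(c(rep(0, 50), rep(10, 50)))
  onset <- detect_switch_onset(a, f, c(0, 2000))
  expect_equal(onset, 50 * 20 + 10)  # first bin where F - A > 2.5 Hz
  # identical PSTHs -> no onset
  expect_true(is.na(detect_switch_onset(a, a, c(0, 2000))))
  # rescaling both PSTHs leaves the onset unchanged
  a2 <- a; f2 <- f
  a2$rate <- a2$rate * 37.5; f2$rate <- f2$rate * 37.5
  expect_equal(detect_switch_onset(a2, f2, c(0, 2000)), onset)
  expect_error(detect_switch_onset(a, bare_psth(rep(0, 30)), c(0, 2000)),
               "bin edges")
})

test_that("fixtures classify into their constructed categories", {
  cases <- list("ideal-switch" = "Switch",
                "oscillating-reciprocal" = "Intermittent",
                "silent" = "None",
                "baseline-only" = "None")
  for (kind in names(cases)) {
    fx <- make_fixture(kind, seed = 4)
    pa <- compute_psth(fx, "Assessment")
    pf <- compute_psth(fx, "Flight")
    cl <- classify_trial(pa, pf, fx$schedule, 1)
    expect_equal(cl$label, cases[[kind]], label = kind)
  }
  # the ideal switch satisfies every criterion individually
  fx <- make_fixture("ideal-switch", seed = 4)
  cl <- classify_trial(compute_psth(fx, "Assessment"),
                       compute_psth(fx, "Flight"), fx$schedule, 1)
  expect_true(all(cl$criteria))
  # the oscillating fixture has at least two reciprocal onsets
  fx <- make_fixture("oscillating-reciprocal", seed = 4)
  cl <- classify_trial(compute_psth(fx, "Assessment"),
                       compute_psth(fx, "Flight"), fx$schedule, 1)
  expect_gte(cl$n_onset_events, 2)
})

test_that("classification is invariant to neuron relabeling and rescaling", {
  fx <- make_fixture("ideal-switch", seed = 9)
  pa <- compute_psth(fx, "Assessment"); pf <- compute_psth(fx, "Flight")
  base <- classify_trial(pa, pf, fx$schedule, 1)
  # permute neuron identities within each population
  fx2 <- fx
  perm <- c(sample(1:100), 100 + sample(1:100))
  fx2$spikes$neuron_id <- perm[fx2$spikes$neuron_id]
  cl2 <- classify_trial(compute_psth(fx2, "Assessment"),
                        compute_psth(fx2, "Flight"), fx2$schedule, 1)
  expect_equal(cl2$label, base$label)
  expect_equal(cl2$criteria, base$criteria)
  # uniform rescaling of both PSTHs
  pa3 <- pa; pf3 <- pf
  pa3$rate <- pa3$rate * 3.7; pf3$rate <- pf3$rate * 3.7
  cl3 <- classify_trial(pa3, pf3, fx$schedule, 1)
  expect_equal(cl3$label, base$label)
  expect_equal(cl3$criteria, base$criteria)
})

test_that("switch-triggered averages are max-normalized and idempotent", {
  # a single trial is its own normalized window: peak exactly 1
  one_trial <- make_fixture("ideal-switch", seed = 5)
  sta1 <- switch_triggered_average(one_trial)
  expect_false(sta1$empty)
  expect_equal(max(sta1$flight), 1)
  expect_equal(max(sta1$assessment), 1)
  # averaging normalized windows keeps the peak at or just below 1
  fx <- make_fixture("ideal-switch", schedule = session_schedule(n_trials = 2),
                     seed = 5)
  sta <- switch_triggered_average(fx)
  expect_false(sta$empty)
  expect_length(sta$onsets_ms, 2)
  expect_gt(max(sta$flight), 0.8)
  expect_lte(max(sta$flight), 1)
  expect_lte(max(sta$assessment), 1)
  # no onsets -> flagged empty, not an error
  silent <- make_fixture("silent", seed = 5)
  expect_true(switch_triggered_average(silent)$empty)
  # single-neuron variant returns one normalized trace
  one <- switch_triggered_average(fx, neuron_id = 150)
  expect_false(one$empty)
  expect_lte(max(one$neuron, na.rm = TRUE), 1)
})

test_that("the hard-threshold oracle yields exact thresholding statistics", {
  theta_in <- 100
  slopes <- c(13, 16, 20, 25)
  recs <- lapply(slopes, function(a) {
    make_fixture("ideal-switch", seed = 2, onset_frac = theta_in / (10 * a),
                 profile = rate_profile(f_max = 10 * a))
  })
  la <- latency_analysis(recs, bin = 10)
  expect_false(la$insufficient)
  # latency decreases strictly with slope: Spearman rho = -1
  expect_equal(la$rho, -1)
  # latency * slope is theta_in - f_baseline up to one PSTH bin
  lat_slope <- la$table$latency_s * la$table$slope
  expect_lt(diff(range(lat_slope)) / mean(lat_slope), 0.01)
  expect_equal(mean(lat_slope), theta_in - 40, tolerance = 2)
  # the input rate at onset is the threshold, with < 1% dispersion
  expect_lt(la$input_rate_cv, 0.01)
  expect_equal(mean(la$table$input_rate_at_onset), theta_in, tolerance = 2)
})

test_that("latency analysis flags insufficient slope coverage", {
  recs <- lapply(c(16, 20), function(a) {
    make_fixture("ideal-switch", seed = 2, profile = rate_profile(f_max = 10 * a))
  })
  expect_true(latency_analysis(recs)$insufficient)
})

test_that("parameter sweeps are deterministic and record failures", {
  grid <- data.frame(r_input = 0.5, r_feedback = 2.5)
  a <- run_sweep("model1", grid, seeds = 1)
  b <- run_sweep("model1", grid, seeds = 1)
  expect_equal(nrow(a$table), 1)
  expect_identical(a$table, b$table)
  # an invalid grid point becomes a failed row, the sweep continues
  bad <- data.frame(r_input = c(0.5, 0.5), tau_rebound = c(10, -5))
  sw <- suppressWarnings(run_sweep("model3", bad, seeds = 1))
  expect_equal(nrow(sw$table), 2)
  expect_true(any(!sw$table$ok))
  expect_true(any(sw$table$ok))
})

test_that("PCA projection passes 3-D spaces through and reduces higher ones", {
  tab3 <- data.frame(a = runif(10), b = runif(10), c = runif(10),
                     seed = 1, label = "None", ok = TRUE)
  p3 <- pca_project(tab3, param_cols = c("a", "b", "c"))
  expect_true(p3$passthrough)
  expect_equal(p3$coords, as.matrix(tab3[, 1:3]))

  set.seed(8)
  tab4 <- data.frame(a = runif(40), b = runif(40), c = runif(40),
                     d = 5, label = "x", ok = TRUE)
  p4 <- pca_project(tab4, param_cols = c("a", "b", "c", "d"))
  expect_false(p4$passthrough)
  expect_equal(ncol(p4$coords), 3)
  # explained variance is non-increasing
  expect_true(all(diff(p4$explained_variance) <= 1e-12))
  # the constant dimension has (near-)zero loadings in every component
  expect_true(all(abs(p4$loadings["d", ]) < 1e-8))
})
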