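test_that("engine spike times match the brute-force reference on a chain", {
  net <- chain_network()
  # a burst train dense enough to drive the whole chain
  input <- sort(c(seq(5, 200, by = 4), seq(300, 500, by = 2.5)))
  sched <- short_schedule(1)
  sim <- run_simulation(net, sched, rate_profile(), seed = 1,
                        input = list(input))
  ref <- reference_chain_run(input, net, duration_ms = 1000)
  expect_gt(nrow(ref), 5)
  expect_true(any(ref$neuron_id == 3))  # signal reached the chain end
  expect_equal(nrow(sim$spikes), nrow(ref))
  for (i in 1:3) {
    a <- sim$spikes$time_ms[sim$spikes$neuron_id == i]
    b <- ref$time_ms[ref$neuron_id == i]
    expect_equal(length(a), length(b))
    expect_true(all(abs(a - b) < 0.1))
  }
})

test_that("causality: spikes propagate no earlier than spike + delay", {
  net <- chain_network(d1 = 2, d2 = 3)
  input <- seq(10, 400, by = 3)
  sim <- run_simulation(net, short_schedule(1), rate_profile(), seed = 1,
                        input = list(input))
  sp <- sim$spikes
  t1 <- sp$time_ms[sp$neuron_id == 1]
  t2 <- sp$time_ms[sp$neuron_id == 2]
  t3 <- sp$time_ms[sp$neuron_id == 3]
  expect_gt(length(t3), 0)
  expect_gte(min(t1), min(input) + 0)
  expect_gte(min(t2), min(t1) + 2)
  expect_gte(min(t3), min(t2) + 3)
})

test_that("a fully decoupled network only fires from background noise", {
  cfg <- circuit_config("model1", constants = list(
    w_amygdala = 1e-6, w_core_core = 1e-6, w_core_shell = 1e-6,
    w_shell_core = 1e-6, w_input = 1e-6))
  net <- build_circuit(cfg, seed = 1)
  sim <- run_simulation(net, short_schedule(5), rate_profile(), seed = 1)
  counts <- table(factor(sim$spikes$population, names(sim$populations)))
  # amygdala has no noise source, so it stays silent
  expect_equal(unname(counts["Amygdala"]), 0L)
  # core and shell fire spontaneously at modest rates (< 5 Hz per neuron)
  expect_lt(counts["Assessment"] / 100 / 5, 5)
  expect_lt(counts["ShellA"] / 20 / 5, 10)
})

test_that("identical seed and config give bit-identical records", {
  net <- build_circuit(circuit_config("model1"), seed = 3)
  a <- run_simulation(net, short_schedule(2), rate_profile(), seed = 7)
  b <- run_simulation(net, short_schedule(2), rate_profile(), seed = 7)
  expect_identical(a$spikes, b$spikes)
  c <- run_simulation(net, short_schedule(2), rate_profile(), seed = 8)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("halving dt changes population rates by less than 2%", {
  # deterministic feedforward configuration: no noise, non-probabilistic
  # release, shared precomputed input, and the recurrent/feedback loops
  # silenced, so the comparison isolates integration error (a recurrent
  # network amplifies spike-time quantization chaotically and has no
  # deterministic dt limit)
  cfg <- circuit_config("model1",
                        core = core_membrane(noise_rate = 0),
                        shell = shell_membrane(noise_rate = 0),
                        constants = list(p_release = 1, w_core_core = 0,
                                         w_core_shell = 0, w_shell_core = 0))
  net <- build_circuit(cfg, seed = 2)
  sched <- session_schedule(n_trials = 1)
  input <- generate_input(sched, rate_profile(), n_inputs = 100, seed = 5)
  r1 <- run_simulation(net, sched, rate_profile(), seed = 5, dt = 0.1,
                       input = input)
  r2 <- run_simulation(net, sched, rate_profile(), seed = 5, dt = 0.05,
                       input = input)
  for (pop in c("Amygdala", "Assessment", "Flight")) {
    n1 <- sum(r1$spikes$population == pop)
    n2 <- sum(r2$spikes$population == pop)
    expect_gt(n1, 100)
    expect_lt(abs(n1 - n2) / n1, 0.02)
  }
})

test_that("spike records round-trip exactly through the TSV exporter", {
  net <- build_circuit(circuit_config("model3", r_input = 0.7), seed = 1)
  sim <- run_simulation(net, short_schedule(2), rate_profile(), seed = 1)
  dir <- withr::local_tempdir()
  export_record(sim, dir)
  back <- read_record(dir)
  expect_equal(back$spikes, sim$spikes)
  expect_equal(back$populations, sim$populations)
  expect_equal(back$duration_ms, sim$duration_ms)
  expect_equal(back$meta$config_hash, sim$meta$config_hash)
  # an empty record still writes valid files
  empty <- sim
  empty$spikes <- sim$spikes[0, ]
  dir2 <- withr::local_tempdir()
  export_record(empty, dir2)
  expect_equal(nrow(read_record(dir2)$spikes), 0)
})

test_that("the metadata hash tracks configuration changes", {
  net <- build_circuit(circuit_config("model1"), seed = 1)
  a <- run_simulation(net, short_schedule(1), rate_profile(), seed = 1)
  b <- run_simulation(net, short_schedule(1), rate_profile(), seed = 2)
  d <- run_simulation(net, short_schedule(1), rate_profile(f_max = 150),
                      seed = 1)
  expect_false(a$meta$config_hash == b$meta$config_hash)
  expect_false(a$meta$config_hash == d$meta$config_hash)
  a2 <- run_simulation(net, short_schedule(1), rate_profile(), seed = 1)
  expect_equal(a$meta$config_hash, a2$meta$config_hash)
})
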