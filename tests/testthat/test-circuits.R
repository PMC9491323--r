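test_that("projection sampling matches Bernoulli statistics", {
  set.seed(1)
  none <- sample_projection(1:10, 11:20, p = 0, weight = 1, delay = 1)
  expect_equal(nrow(none), 0)
  full <- sample_projection(1:10, 11:20, p = 1, weight = 1, delay = 1)
  expect_equal(nrow(full), 100)
  big <- sample_projection(1:100, 101:200, p = 0.2, weight = 1, delay = 1)
  # 99% binomial interval around 2000 edges
  expect_gt(nrow(big), qbinom(0.005, 10000, 0.2))
  expect_lt(nrow(big), qbinom(0.995, 10000, 0.2))
  # truncated-normal weights stay positive; uniform delays stay in range
  w <- sample_projection(1:50, 1:50, p = 0.5,
                         weight = list(mean = 100, sd = 50),
                         delay = c(1, 3))
  expect_true(all(w$weight > 0))
  expect_true(all(w$delay >= 1 & w$delay <= 3))
})

test_that("model variants realize their population and wiring contracts", {
  cfgs <- list(model1 = circuit_config("model1"),
               model2 = circuit_config("model2"),
               hybrid = circuit_config("hybrid"),
               model3 = circuit_config("model3"),
               model4 = circuit_config("model4"))
  for (nm in names(cfgs)) {
    net <- build_circuit(cfgs[[nm]], seed = 2)
    pops <- net$populations
    expect_equal(pops$size[pops$name == "Amygdala"], 100L)
    expect_equal(pops$size[pops$name == "Assessment"], 100L)
    if (nm == "model4") {
      expect_equal(pops$size[pops$name == "Shell"], 40L)
    } else {
      expect_equal(pops$size[pops$name == "ShellA"], 20L)
    }
    # no amygdala-amygdala edges
    amy <- population_ids(net, "Amygdala")
    expect_equal(sum(net$edges$pre %in% amy & net$edges$post %in% amy), 0)
    # sign constraints: shell edges inhibitory, all others excitatory
    shell_ids <- unlist(lapply(intersect(pops$name, c("ShellA", "ShellF",
                                                      "Shell")),
                               population_ids, network = net))
    pre_shell <- net$edges$pre %in% shell_ids
    expect_true(all(net$edges$weight[pre_shell] <= 0))
    expect_true(all(net$edges$weight[!pre_shell] >= 0))
  }
})

test_that("exclusive feedback wiring has no same-side shell edges", {
  for (variant in c("model1", "model2", "hybrid", "model3")) {
    net <- build_circuit(circuit_config(variant), seed = 3)
    asm <- population_ids(net, "Assessment")
    fly <- population_ids(net, "Flight")
    sha <- population_ids(net, "ShellA")
    shf <- population_ids(net, "ShellF")
    expect_equal(sum(net$edges$pre %in% sha & net$edges$post %in% asm), 0)
    expect_equal(sum(net$edges$pre %in% shf & net$edges$post %in% fly), 0)
    expect_gt(sum(net$edges$pre %in% sha & net$edges$post %in% fly), 0)
    expect_gt(sum(net$edges$pre %in% shf & net$edges$post %in% asm), 0)
  }
  # model4 wires shell to both core populations
  net4 <- build_circuit(circuit_config("model4"), seed = 3)
  sh <- population_ids(net4, "Shell")
  asm <- population_ids(net4, "Assessment")
  fly <- population_ids(net4, "Flight")
  expect_gt(sum(net4$edges$pre %in% sh & net4$edges$post %in% asm), 0)
  expect_gt(sum(net4$edges$pre %in% sh & net4$edges$post %in% fly), 0)
})

test_that("r_input scales amygdala-to-Flight density; r_feedback scales weights", {
  net0 <- build_circuit(circuit_config("model1", r_input = 0), seed = 4)
  m0 <- connectivity_matrix(net0)
  expect_equal(m0["Amygdala", "Flight"], 0)
  expect_equal(m0["Amygdala", "Amygdala"], 0)

  net <- build_circuit(circuit_config("model1", r_input = 0.5), seed = 4)
  m <- connectivity_matrix(net)
  k <- circuit_defaults()
  # realized densities within binomial sampling error of p_in and p_in/2
  expect_equal(m["Amygdala", "Flight"], k$p_in / 2, tolerance = 0.1)
  expect_equal(m["Amygdala", "Assessment"], k$p_in, tolerance = 0.1)
  expect_equal(m["Amygdala", "Flight"] / m["Amygdala", "Assessment"], 0.5,
               tolerance = 0.15)

  k <- circuit_defaults()
  shf <- population_ids(net, "ShellF")
  sha <- population_ids(net, "ShellA")
  w_onto_asm <- net$edges$weight[net$edges$pre %in% shf]
  w_onto_fly <- net$edges$weight[net$edges$pre %in% sha]
  expect_equal(unique(w_onto_asm), -k$w_shell_core * 2.5)
  expect_equal(unique(w_onto_fly), -k$w_shell_core)
})

test_that("rebound relay equips exactly the inhibitory inputs onto Flight", {
  net1 <- build_circuit(circuit_config("model1"), seed = 5)
  expect_equal(sum(net1$edges$rebound), 0)
  for (variant in c("model3", "model4")) {
    net <- build_circuit(circuit_config(variant), seed = 5)
    fly <- population_ids(net, "Flight")
    reb <- net$edges[net$edges$rebound, ]
    expect_gt(nrow(reb), 0)
    expect_true(all(reb$post %in% fly))
    expect_true(all(reb$weight < 0))
    # every inhibitory edge onto Flight carries the relay
    inh_onto_fly <- net$edges$weight < 0 & net$edges$post %in% fly
    expect_equal(sum(inh_onto_fly), nrow(reb))
  }
})

test_that("TM synapses sit on all core outputs in model2 and hybrid", {
  for (variant in c("model2", "hybrid")) {
    net <- build_circuit(circuit_config(variant), seed = 6)
    core <- c(population_ids(net, "Assessment"), population_ids(net, "Flight"))
    from_core <- net$edges$pre %in% core
    expect_true(all(net$edges$kind[from_core] == "tm"))
    expect_true(all(net$edges$kind[!from_core] == "static"))
  }
  net1 <- build_circuit(circuit_config("model1"), seed = 6)
  expect_true(all(net1$edges$kind == "static"))
})

test_that("network construction is deterministic under a fixed seed", {
  a <- build_circuit(circuit_config("model3"), seed = 7)
  b <- build_circuit(circuit_config("model3"), seed = 7)
  expect_identical(a$edges, b$edges)
  c <- build_circuit(circuit_config("model3"), seed = 8)
  expect_false(identical(a$edges, c$edges))
})

test_that("out-of-range ratios warn but do not error", {
  expect_warning(circuit_config("model1", r_input = 1.5), "r_input")
  expect_warning(circuit_config("model1", r_feedback = 30), "r_feedback")
})
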