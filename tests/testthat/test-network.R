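test_that("wiring follows the connection statistics and is reproducible", {
  counts <- vapply(1:200, function(s) {
    nrow(build_network(network_config(seed = s))$synapses) / 4
  }, numeric(1))
  expect_gt(mean(counts), 45)
  expect_lt(mean(counts), 55)
  n1 <- build_network(network_config(seed = 42))
  n2 <- build_network(network_config(seed = 42))
  expect_identical(n1$synapses, n2$synapses)
  # initial weights exactly at the configured strength, per projection
  wt <- weights_table(n1)
  expect_true(all(wt$mean_weight_uS == 0.006))
  # no recurrent or within-area connections
  pre_groups <- n1$neurons$group[n1$synapses$pre]
  post_groups <- n1$neurons$group[n1$synapses$post]
  expect_true(all(grepl("^VC", pre_groups)))
  expect_true(all(grepl("^PMC", post_groups)))
})

test_that("a quiescent network stays silent and weights never move unattended", {
  set.seed(1)
  st <- build_network(network_config(seed = 1, background_rate = 0))
  st <- run_interval(st, NULL, 1000)
  expect_equal(nrow(spike_log(st)), 0)

  set.seed(2)
  st2 <- build_network(network_config(seed = 2))
  w0 <- st2$synapses$weight
  st2 <- run_interval(st2, stimulus_spec("VC1", 2000), 500)
  expect_gt(nrow(spike_log(st2)), 0)
  expect_identical(st2$synapses$weight, w0)  # plasticity disabled
})

test_that("targeted drive excites only its column and runs are deterministic", {
  run_once <- function() {
    set.seed(7)
    st <- build_network(network_config(seed = 7))
    st <- run_interval(st, stimulus_spec("VC1", 2000), 500)
    spike_log(st)
  }
  log <- run_once()
  expect_gt(group_rate(log, "VC1", c(0, 500)), 2)
  expect_equal(group_rate(log, "VC2", c(0, 500)), 0)
  expect_identical(run_once(), log)
  # zero-rate stimulus drives nothing
  set.seed(8)
  st <- build_network(network_config(seed = 8, background_rate = 0))
  st <- run_interval(st, stimulus_spec("VC1", 0), 300)
  expect_equal(nrow(spike_log(st)), 0)
})

test_that("group rates follow the spikes-per-neuron-time definition", {
  log <- tibble::tibble(
    time_ms = seq(25, 500, length.out = 20),
    neuron = rep(21:30, 2), group = "PMC1"
  )
  expect_equal(group_rate(log, "PMC1", c(0, 500)), 4.0)
  expect_equal(group_rate(tibble::tibble(time_ms = numeric(),
                                         neuron = integer(),
                                         group = character()),
                          "PMC2", c(0, 500)), 0)
  expect_error(group_rate(log, "XYZ", c(0, 500)), "Unknown group")
})

test_that("single causal volley pairs potentiate by the closed-form amount", {
  # weights start at zero so spiking is driven purely by the external
  # volleys (no synaptic cross-talk); a long refractory period prevents
  # burst doubles from residual conductance
  cfg <- network_config(seed = 3, background_rate = 0, initial_weight = 0,
                        lif = lif_params(refractory = 8))
  set.seed(3)
  st <- build_network(cfg)
  st <- set_plasticity(st, TRUE)
  # one synchronized VC1 volley, PMC1 following at exactly +5 ms
  stim <- dplyr::bind_rows(
    stimulus_spec("VC1", 10, kind = "volley_periodic", weight = 0.05,
                  delay_lo = 0, delay_hi = 0, volley_id = 1L),
    stimulus_spec("PMC1", 10, kind = "volley_periodic", weight = 0.05,
                  delay_lo = 5, delay_hi = 5, volley_id = 1L)
  )
  st <- run_interval(st, stim, 99)  # one event at t = 50
  log <- spike_log(st)
  t_vc <- unique(log$time_ms[log$group == "VC1"])
  t_pm <- unique(log$time_ms[log$group == "PMC1"])
  expect_length(t_vc, 1)
  expect_length(t_pm, 1)
  dt_pair <- t_vc - t_pm  # pre minus post, negative
  expected <- stdp_delta(dt_pair) / 100 * cfg$w_max
  sy <- st$synapses
  w11 <- sy$weight[sy$projection == "VC1->PMC1"]
  expect_equal(unique(round(w11, 12)), round(expected, 12))
  # depression-only projections ignore the causal pairing entirely
  expect_true(all(sy$weight[sy$projection == "VC1->PMC2"] == 0))
})

test_that("incremental pairing equals chronological replay from the spike log", {
  for (pairing in c("nearest", "all")) {
    cfg <- network_config(seed = 11, pairing = pairing)
    set.seed(11)
    st <- build_network(cfg)
    w0 <- st$synapses
    st <- set_plasticity(st, TRUE)
    stim <- dplyr::bind_rows(
      stimulus_spec("VC1", 1500),
      stimulus_spec("PMC1", 500)
    )
    st <- run_interval(st, stim, 2000)
    log <- spike_log(st)
    expect_gt(nrow(log), 50)
    replayed <- stdp_replay(log, w0, cfg$stdp, cfg$w_max, pairing = pairing)
    expect_equal(st$synapses$weight, replayed, tolerance = 1e-10)
  }
})

test_that("weights stay inside their bounds under heavy drive", {
  cfg <- network_config(seed = 5)
  set.seed(5)
  st <- build_network(cfg)
  st <- set_plasticity(st, TRUE)
  stim <- dplyr::bind_rows(
    stimulus_spec("VC1", 4000), stimulus_spec("VC2", 4000),
    stimulus_spec("PMC1", 2000), stimulus_spec("PMC2", 2000)
  )
  st <- run_interval(st, stim, 1500)
  expect_true(all(st$synapses$weight >= 0))
  expect_true(all(st$synapses$weight <= cfg$w_max))
  expect_true(all(st$g >= 0))
})

test_that("mean_weight reports projections and rejects unknown ones", {
  st <- build_network(network_config(seed = 9))
  expect_equal(mean_weight(st, "VC1", "PMC1"), 0.006)
  expect_error(mean_weight(st, "PMC1", "VC1"), "no synapses")
})
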