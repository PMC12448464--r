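# Simulation engine: synaptic closed forms, determinism, delivery timing,
# superposition, sparsity, and disinhibition.

test_that("the NMDA Mg block follows the printed sigmoid", {
  expect_equal(mg_block(0), 1 / 1.28)
  expect_equal(mg_block(-70), 1 / (1 + 0.28 * exp(0.04 * 70)))
  expect_gt(mg_block(40), mg_block(-80))  # relief with depolarization
})

test_that("the synaptic kernel peaks at the closed-form time with unit height", {
  tr <- 0.5; td <- 3.5
  tp <- syn_peak_time(tr, td)
  expect_equal(tp, log(td / tr) * td * tr / (td - tr))
  expect_equal(syn_kernel(tp, tr, td), 1)
  tt <- seq(0, 30, 0.01)
  expect_lte(max(syn_kernel(tt, tr, td)), 1 + 1e-12)
  expect_equal(tt[which.max(syn_kernel(tt, tr, td))], tp, tolerance = 0.01)
})

test_that("synaptic current sums receptors with the depolarizing convention", {
  rec <- data.frame(g = c(1e-6, 2e-6), E_syn = c(0, -90),
                    nmda = c(FALSE, FALSE))
  I <- synaptic_current(-70, rec)
  expect_equal(I, 1e-6 * 70 + 2e-6 * (-20))
  expect_equal(synaptic_current(-70, rec[0, ]), 0)
  rec_n <- data.frame(g = 1e-6, E_syn = 0, nmda = TRUE)
  expect_equal(synaptic_current(0, rec_n), 0)  # no driving force at E_syn
  expect_equal(synaptic_current(-60, rec_n), 1e-6 * mg_block(-60) * 60)
})

test_that("a single delivered spike reproduces the kernel peak at gbar", {
  tn <- tiny_network(c(PP_GC = 1))
  P <- manual_pattern(list(c(600), numeric(0), numeric(0)))
  sim <- simulate_network(tn$net, P, tn$cfg, record_g = "PP_GC")
  g <- sim$g_trace[, 1] * 1e6  # mS -> nS
  tr <- tn$cfg$synapses$tau_rise[1]; td <- tn$cfg$synapses$tau_decay[1]
  delay <- tn$cfg$synapses$delay[1]
  expect_equal(max(g), 1, tolerance = 5e-3)  # peak equals gbar = 1 nS
  t_peak <- which.max(g) * 0.1
  expect_equal(t_peak, 600 + delay + syn_peak_time(tr, td), tolerance = 0.2)
})

test_that("conductance responses superpose linearly", {
  tn <- tiny_network(c(PP_GC = 1))
  P_a <- manual_pattern(list(c(600), numeric(0), numeric(0)))
  P_b <- manual_pattern(list(c(640), numeric(0), numeric(0)))
  P_ab <- manual_pattern(list(c(600, 640), numeric(0), numeric(0)))
  g_a <- simulate_network(tn$net, P_a, tn$cfg, record_g = "PP_GC")$g_trace[, 1]
  g_b <- simulate_network(tn$net, P_b, tn$cfg, record_g = "PP_GC")$g_trace[, 1]
  g_ab <- simulate_network(tn$net, P_ab, tn$cfg, record_g = "PP_GC")$g_trace[, 1]
  expect_equal(g_ab, g_a + g_b, tolerance = 1e-12)
})

test_that("an unconnected network stays silent", {
  tn <- tiny_network()
  P <- generate_base_pattern(3, 8, 2000, seed = 2)
  sim <- simulate_network(tn$net, P, tn$cfg)
  expect_true(all(vapply(sim$spikes, nrow, integer(1)) == 0))
})

test_that("strong feedforward drive time-locks granule spikes to the input", {
  tn <- tiny_network(c(PP_GC = 40))  # far suprathreshold EPSP
  P <- manual_pattern(list(c(600, 900, 1400), numeric(0), numeric(0)))
  sim <- simulate_network(tn$net, P, tn$cfg)
  gc <- sim$spikes$GC
  inputs <- c(600, 900, 1400)
  delay <- tn$cfg$synapses$delay[1]
  lag <- vapply(gc$time, function(t) t - max(inputs[inputs < t]), numeric(1))
  # every spike sits shortly after an input (residual conductance can add a
  # refractory-limited doublet, never a free-running response: the synaptic
  # kernel has decayed to ~2% within 15 ms while inputs are 300+ ms apart)
  expect_true(all(lag > delay))
  expect_true(all(lag < delay + 15))
  # each granule cell responds to each input with at least one locked spike
  for (i in seq_len(tn$net$sizes[["GC"]]))
    for (t0 in inputs)
      expect_true(any(gc$neuron == i & gc$time > t0 + delay &
                        gc$time <= t0 + delay + 3))
})

test_that("simulation is a pure function of its inputs", {
  pops <- test_pops()
  cfg <- test_cfg()
  net <- build_network(pops, cfg, seed = 5)
  P <- generate_base_pattern(cfg$input$n_trains, 8, 2000, seed = 3)
  s1 <- simulate_network(net, P, cfg)
  s2 <- simulate_network(net, P, cfg)
  expect_identical(s1$spikes, s2$spikes)
  # noisy runs reproduce per seed and differ across seeds
  n1 <- simulate_network(net, P, cfg, noise_sigma = 3, seed = 41)
  n2 <- simulate_network(net, P, cfg, noise_sigma = 3, seed = 41)
  n3 <- simulate_network(net, P, cfg, noise_sigma = 3, seed = 42)
  expect_identical(n1$spikes, n2$spikes)
  expect_false(identical(n1$spikes, n3$spikes))
})

test_that("sparsity counts active neurons in the analysis window", {
  sim <- structure(list(
    spikes = list(GC = data.frame(neuron = c(1, 1, 2, 3),
                                  time = c(600, 700, 100, 1200)),
                  BC = data.frame(neuron = integer(0), time = numeric(0)),
                  MC = data.frame(neuron = 1, time = 1000),
                  HC = data.frame(neuron = integer(0), time = numeric(0))),
    window = c(500, 2000), duration = 2000,
    sizes = c(GC = 10L, BC = 4L, MC = 1L, HC = 2L), seed = NULL),
    class = "dg_sim")
  # neuron 2's only spike (t = 100) precedes the analysis window
  expect_equal(compute_sparsity(sim, "GC"), 1 - 2 / 10)
  expect_equal(compute_sparsity(sim, "BC"), 1)
  expect_equal(compute_sparsity(sim, "MC"), 0)
  expect_equal(sim_rate_vector(sim, "GC")[1], 2 / 1.5)
})

test_that("removing basket-cell inhibition never reduces granule output", {
  search <- test_search()
  ids <- which(search$valid)
  expect_gte(length(ids), 1)
  net <- dgsep:::candidate_network(search, ids[1])
  P <- search$patterns[[1]]
  base <- simulate_network(net, P, test_cfg())
  dis <- simulate_network(delete_subtype(net, "BC"), P, test_cfg())
  expect_gte(nrow(dis$spikes$GC), nrow(base$spikes$GC))
})

test_that("HIPP cells are driven only by the perforant path", {
  search <- test_search()
  ids <- which(search$valid)
  net <- dgsep:::candidate_network(search, ids[1])
  P <- search$patterns[[2]]
  base <- simulate_network(net, P, test_cfg())
  for (st in c("BC", "MC")) {
    d <- simulate_network(delete_subtype(net, st), P, test_cfg())
    expect_identical(d$spikes$HC, base$spikes$HC)
  }
})
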