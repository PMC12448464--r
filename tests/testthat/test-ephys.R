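# Electrophysiological protocols: closed-form passive limits, fit recovery
# on synthetic traces, adaptation signatures, and bound validation.

test_that("passive membrane time constant recovers R_m * C_m", {
  p <- passive_params(R_m = 30, A = 1e-4, C_m = 1)
  tm <- measure_tau_m(p)
  expect_true(tm$valid)
  expect_equal(tm$tau_m, 30, tolerance = 0.02)  # kOhm cm^2 * uF/cm^2 = ms
})

test_that("exponential fit recovers known parameters from a synthetic trace", {
  t <- seq(0, 1500, 0.1)
  V <- 6.5 * (1 - exp(-t / 27)) + (-71)
  fit <- dgsep:::fit_charging_exponential(t, V, baseline = -71)
  expect_equal(fit$tau_m, 27, tolerance = 1e-3)
  expect_equal(fit$V_inf, 6.5, tolerance = 1e-3)
  expect_equal(fit$V_0, -71, tolerance = 1e-3)
})

test_that("adaptive coupling makes the fitted tau_m deviate from R_m * C_m", {
  p <- neuron_params("GC", C_m = 1, R_m = 30, A = 1e-4, E_l = -75,
                     V_th = 100, Delta_T = 0.5, V_reset = -75, tau_w = 80,
                     alpha = 2e-3, b = 0)
  tm <- measure_tau_m(p)
  expect_true(tm$valid)
  # two-timescale system: single-exponential fit no longer equals R_m C_m
  expect_gt(abs(tm$tau_m - 30), 2)
})

test_that("sag ratio is 1 without adaptation and below 1 with it", {
  p0 <- passive_params(R_m = 25, A = 1e-4)
  s0 <- measure_sag(p0)
  expect_equal(s0$sag, 1, tolerance = 1e-3)
  p1 <- neuron_params("MC", C_m = 1, R_m = 25, A = 1e-4, E_l = -70,
                      V_th = 100, Delta_T = 0.5, V_reset = -75, tau_w = 120,
                      alpha = 1.5e-3, b = 0)
  s1 <- measure_sag(p1)
  expect_lt(s1$sag, 0.98)
  expect_gt(s1$sag, 0)
})

test_that("sag is invariant to pulse amplitude in the passive linear regime", {
  p <- neuron_params("MC", C_m = 1, R_m = 25, A = 1e-4, E_l = -70,
                     V_th = 100, Delta_T = 0.5, V_reset = -75, tau_w = 120,
                     alpha = 1e-3, b = 0)
  # long settling so the slow adaptation mode has fully relaxed and the
  # pre-pulse baseline is stationary
  cfg_slow <- engine_config(settle = 2000)
  pr1 <- dgsep:::pulse_response(p, -50, 1000, cfg_slow)
  pr2 <- dgsep:::pulse_response(p, -100, 1000, cfg_slow)
  sag1 <- (pr1$ss - pr1$baseline) / min(pr1$sim$V[pr1$pulse_i] - pr1$baseline)
  sag2 <- (pr2$ss - pr2$baseline) / min(pr2$sim$V[pr2$pulse_i] - pr2$baseline)
  expect_equal(sag1, sag2, tolerance = 1e-3)
})

test_that("input resistance matches closed forms", {
  p <- passive_params(R_m = 20, A = 1e-4)
  ri <- measure_input_resistance(p)
  expect_true(ri$valid)
  expect_equal(ri$R_in, 200, tolerance = 0.01)  # R_m / A = 200 MOhm

  # deep-subthreshold limit with coupling: R ~ 1 / (g_l + alpha)
  alpha_us <- 2e-3  # uS
  p2 <- neuron_params("GC", C_m = 1, R_m = 20, A = 1e-4, E_l = -70,
                      V_th = 100, Delta_T = 0.5, V_reset = -75, tau_w = 50,
                      alpha = alpha_us, b = 0)
  ri2 <- measure_input_resistance(p2)
  g_l_us <- 1e-4 / 20 * 1e3          # mS -> uS
  expect_equal(ri2$R_in, 1 / (g_l_us + alpha_us), tolerance = 0.02)
})

test_that("regression on synthetic linear V-I data is exact", {
  amps <- seq(-40, 40, 10)
  defl <- 0.21 * amps  # mV per pA -> 210 MOhm
  slope <- stats::coef(stats::lm(defl ~ amps))[2]
  expect_equal(unname(slope) * 1000, 210, tolerance = 1e-9)
})

test_that("firing protocol: subthreshold cells, constant ISIs, adaptation", {
  p_sub <- passive_params(R_m = 20, A = 1e-4)
  ff <- measure_firing_and_sfa(p_sub)
  expect_equal(ff$f50, 0)
  expect_true(is.na(ff$SFA))

  # no adaptation: identical late ISIs, SFA near 1
  p_flat <- neuron_params("BC", C_m = 1, R_m = 15, A = 1e-4, E_l = -65,
                          V_th = -50, Delta_T = 1, V_reset = -58, tau_w = 50,
                          alpha = 0, b = 0)
  ff2 <- measure_firing_and_sfa(p_flat)
  expect_gte(ff2$f150, 3)
  expect_equal(ff2$SFA, 1, tolerance = 0.05)

  # spike-triggered adaptation: first ISI shorter than last
  p_ad <- neuron_params("GC", C_m = 1, R_m = 23, A = 1e-4, E_l = -75,
                        V_th = -52, Delta_T = 2, V_reset = -62, tau_w = 120,
                        alpha = 5e-4, b = 0.026)
  ff3 <- measure_firing_and_sfa(p_ad)
  expect_gte(ff3$f150, 3)
  expect_lt(ff3$SFA, 1)
})

test_that("validation is a strict conjunction over the six bounds", {
  bounds <- list(GC = list(tau_m = c(10, 40), sag = c(0.8, 1),
                           R_in = c(100, 300), SFA = c(0.1, 0.9),
                           f50 = c(0, 5), f150 = c(5, 40)))
  mid <- data.frame(tau_m = 25, sag = 0.9, R_in = 200, SFA = 0.5,
                    f50 = 2, f150 = 20)
  expect_true(validate_neuron(mid, bounds, "GC")$valid)

  over <- mid; over$R_in <- 300 + 1e-9
  expect_false(validate_neuron(over, bounds, "GC")$valid)

  undef <- mid; undef$SFA <- NA
  expect_false(validate_neuron(undef, bounds, "GC")$valid)

  # random vectors against a brute-force conjunction oracle
  set.seed(9)
  for (k in 1:50) {
    m <- data.frame(tau_m = runif(1, 0, 60), sag = runif(1, 0.5, 1.1),
                    R_in = runif(1, 0, 500), SFA = runif(1, 0, 1.2),
                    f50 = sample(0:10, 1), f150 = sample(0:60, 1))
    oracle <- all(vapply(names(bounds$GC), function(nm)
      m[[nm]] >= bounds$GC[[nm]][1] && m[[nm]] <= bounds$GC[[nm]][2],
      logical(1)))
    expect_identical(validate_neuron(m, bounds, "GC")$valid, oracle)
  }
})

test_that("validation is monotone under bound widening", {
  bounds <- list(GC = list(tau_m = c(10, 40), sag = c(0.8, 1),
                           R_in = c(100, 300), SFA = c(0.1, 0.9),
                           f50 = c(0, 5), f150 = c(5, 40)))
  wide <- bounds
  for (nm in names(wide$GC)) wide$GC[[nm]] <- wide$GC[[nm]] + c(-5, 5)
  set.seed(10)
  for (k in 1:30) {
    m <- data.frame(tau_m = runif(1, 0, 60), sag = runif(1, 0.5, 1.1),
                    R_in = runif(1, 0, 500), SFA = runif(1, 0, 1.2),
                    f50 = sample(0:10, 1), f150 = sample(0:60, 1))
    if (validate_neuron(m, bounds, "GC")$valid)
      expect_true(validate_neuron(m, wide, "GC")$valid)
  }
})

test_that("protocols are deterministic", {
  p <- dgsep:::default_neuron_params()$MC
  m1 <- measure_ephys(p)
  m2 <- measure_ephys(p)
  expect_identical(m1, m2)
})
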