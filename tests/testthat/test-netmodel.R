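test_that("uncoupled QIF neurons fire at the closed-form tonic rate", {
  p <- network_params(n = 10, frac_E = 0.5, K = 1, I0_E = 1, I0_I = 1,
                      D_E = 0, D_I = 0, g0_EE = 0, g0_II = 0, g0_EI = 0,
                      g0_IE = 0, A = 0, tau_E = 10, tau_I = 10, dt = 0.001)
  sim <- simulate_network(p, 2)
  pred <- sqrt(1) / (pi * 0.010)
  expect_equal(mean(sim$rates[1:5]), pred, tolerance = 0.02)
  # coarser steps stay within a looser band
  p$dt <- 0.01
  expect_equal(mean(simulate_network(p, 2)$rates[1:5]), pred,
               tolerance = 0.1)
})

test_that("subthreshold drive produces no spikes", {
  p <- network_params(n = 10, frac_E = 0.5, K = 1, I0_E = -0.5,
                      I0_I = -0.5, D_E = 0, D_I = 0, g0_EE = 0, g0_II = 0,
                      g0_EI = 0, g0_IE = 0, A = 0, dt = 0.001)
  expect_equal(nrow(simulate_network(p, 1)$raster), 0)
})

test_that("the same seed reproduces the raster exactly", {
  p <- network_params(n = 80, K = 10, dt = 0.01, seed = 4)
  s1 <- simulate_network(p, 1)
  s2 <- simulate_network(p, 1)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$lfp, s2$lfp)
})

test_that("a single spike produces the closed-form double-exponential current", {
  p <- network_params(n = 10, K = 4, seed = 1)
  raster <- data.frame(neuron = 1L, time_ms = 100)
  out <- synthesize_model_lfp(raster, p, nE = 8, out_degree_EE = rep(3, 8),
                              duration_s = 0.5)
  tt <- seq_len(500) - 100
  gain <- 2 * p$tau_E * p$g0_EE / sqrt(p$K)
  expected <- 3 * synaptic_impulse_response(tt, p$tau_rA, p$tau_dA, gain)
  expect_equal(out$lfp_raw, expected, tolerance = 1e-9)
  # peak lies between the rise and decay constants
  pk <- which.max(out$lfp_raw) - 100
  expect_gt(pk, p$tau_rA)
  expect_lt(pk, p$tau_dA + 1)
  # empty raster gives a null trace
  none <- synthesize_model_lfp(raster[0, ], p, nE = 8, duration_s = 0.2)
  expect_true(all(none$lfp_raw == 0))
})

test_that("online and event-based model LFP agree", {
  # the online trace averages within 1 ms bins while the event-based
  # reconstruction samples instants, so agreement is high but not exact
  p <- network_params(n = 60, K = 8, dt = 0.01, seed = 9, A = 0.2)
  sim <- simulate_network(p, 3, transient_s = 0)
  ev <- synthesize_model_lfp(sim$raster, p, nE = sim$nE,
                             out_degree_EE = sim$out_degree_EE,
                             duration_s = 3)
  n <- min(length(sim$lfp_raw), length(ev$lfp_raw))
  i <- 200:(n - 200)
  expect_gt(cor(sim$lfp_raw[i], ev$lfp_raw[i]), 0.9)
  expect_equal(mean(sim$lfp_raw[i]), mean(ev$lfp_raw[i]), tolerance = 0.05)
})

test_that("spectral entropy separates flat noise from pure tones", {
  set.seed(10)
  fs <- 1000
  t <- seq_len(20 * fs) / fs
  expect_gt(spectral_entropy(rnorm(20 * fs), fs), 0.9)
  expect_lt(spectral_entropy(sin(2 * pi * 60 * t), fs), 0.05)
  two <- sin(2 * pi * 40 * t) + sin(2 * pi * 80 * t)
  expect_equal(spectral_entropy(two, fs), log2(2) / log2(1000),
               tolerance = 0.02)
  expect_error(spectral_entropy(rnorm(100), fs), "10 s")
})

test_that("gamma power ratio is signed exactly as printed", {
  fs <- 1000
  t <- seq_len(10 * fs) / fs
  expect_equal(gamma_power_ratio(sin(2 * pi * 40 * t), fs), 1,
               tolerance = 1e-6)
  expect_equal(gamma_power_ratio(sin(2 * pi * 80 * t), fs), -1,
               tolerance = 1e-6)
  mix <- sin(2 * pi * 40 * t) + sin(2 * pi * 80 * t)
  expect_equal(gamma_power_ratio(mix, fs), 0, tolerance = 1e-3)
})

test_that("spike-train entropy is the binary entropy of p = rate/gamma", {
  expect_equal(spike_train_entropy(40, 80), 1)
  expect_equal(spike_train_entropy(0, 80), 0)
  expect_equal(spike_train_entropy(80, 80), 0)
  expect_equal(spike_train_entropy(20, 80),
               -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_warning(h <- spike_train_entropy(100, 80), "clipping")
  expect_equal(h, 0)
})

test_that("phase concentration measures phasor alignment", {
  expect_equal(phase_concentration(rep(123, 50)), 1)
  expect_equal(phase_concentration(c(0, 180)), 0, tolerance = 1e-12)
  expect_lt(phase_concentration(seq(0.5, 360, by = 1)), 1e-10)
  expect_error(phase_concentration(numeric(0)), "no spikes")
})

test_that("regime sweep returns one indicator row per grid point", {
  base <- network_params(n = 60, dt = 0.02, seed = 2)
  sw <- sweep_regimes(c(10, 20), 0.01, base = base, duration_s = 11)
  expect_equal(nrow(sw), 2)
  expect_true(all(c("spectral_entropy", "r_gamma", "vI_sd",
                    "spike_entropy") %in% names(sw)))
  expect_true(all(is.finite(sw$spectral_entropy)))
  sw1 <- sweep_regimes(15, 0.01, base = base, duration_s = 11)
  expect_equal(nrow(sw1), 1)
})

test_that("model elements and spike decoding produce a coherent report", {
  p <- network_params(n = 150, dt = 0.02, seed = 5)
  sim <- simulate_network(p, 12)
  els <- model_gamma_elements(sim)
  expect_gt(nrow(els), 50)
  expect_true(all(table(els$cycle_id) <= 4))
  rep0 <- decode_spiking(els, sim, neurons = seq_len(8),
                         config = decoder_config(max_learners = 30,
                                                 seed = 1))
  expect_true(all(c("tp", "tn", "precision", "recall", "decodable",
                    "phase_concentration") %in% names(rep0)))
  done <- rep0[!is.na(rep0$tp), ]
  expect_true(all(done$tp >= 0 & done$tp <= 1))
  expect_true(all(done$tn >= 0 & done$tn <= 1))
  expect_equal(done$decodable, done$tp > 0.6 & done$tn > 0.6)
})
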