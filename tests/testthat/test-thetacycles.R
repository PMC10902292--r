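fs <- 1000

make_warped_wave <- function(dur_s, period, asym, fs = 1000) {
  tt <- seq_len(dur_s * fs) / fs
  wave <- numeric(length(tt))
  for (t0 in seq(0, dur_s, by = period)) {
    cyc <- gammel:::theta_cycle_times(t0, period, asym)
    i <- which(tt >= cyc$t0 & tt < cyc$t1)
    if (length(i)) wave[i] <- gammel:::theta_cycle_wave(tt[i], cyc)
  }
  wave
}

test_that("a 10 Hz sinusoid yields ~99 cycles of ~100 ms", {
  t <- seq_len(10 * fs) / fs
  cyc <- detect_candidate_cycles(sin(2 * pi * 10 * t), fs)
  expect_gte(nrow(cyc), 97)
  expect_lte(nrow(cyc), 100)
  expect_true(all(abs(cyc$duration_ms - 100) <= 2))
  expect_true(all(abs(cyc$frequency - 10) < 0.5))
})

test_that("constant and too-short signals give no cycles", {
  expect_equal(nrow(detect_candidate_cycles(rep(1, 1000), fs)), 0)
  expect_equal(nrow(detect_candidate_cycles(numeric(2), fs)), 0)
})

test_that("asymmetry recovers the rise/decay ratio of a warped wave", {
  # decay 60 ms, rise 40 ms -> asymmetry 40/60
  wave <- make_warped_wave(5, 0.1, asym = 40 / 60)
  cyc <- detect_candidate_cycles(wave, fs)
  expect_gt(nrow(cyc), 30)
  expect_equal(median(cyc$asymmetry), 40 / 60, tolerance = 0.06)
  # landmarks are ordered within each cycle
  with(cyc, expect_true(all(start_peak < desc_flank &
                              desc_flank < trough &
                              trough < asc_flank & asc_flank < end_peak)))
})

test_that("waveform phase hits the landmark values and interpolates", {
  cyc <- data.frame(cycle_id = 1, start_peak = 100, desc_flank = 130,
                    trough = 160, asc_flank = 200, end_peak = 240)
  expect_equal(waveform_phase(cyc, 100), 0)
  expect_equal(waveform_phase(cyc, 130), 90)
  expect_equal(waveform_phase(cyc, 160), 180)
  expect_equal(waveform_phase(cyc, 200), 270)
  expect_equal(waveform_phase(cyc, 240), 360)
  # midway between ascending flank and end peak -> 315
  expect_equal(waveform_phase(cyc, 220), 315)
  expect_error(waveform_phase(cyc, 99), "outside")
})

test_that("waveform phase is monotone and close to Hilbert phase for a sinusoid", {
  t <- seq_len(3 * fs) / fs
  x <- cos(2 * pi * 8 * t)
  cyc <- detect_candidate_cycles(x, fs)
  k <- 5
  idx <- cyc$start_peak[k]:cyc$end_peak[k]
  ph <- waveform_phase(cyc[k, ], idx)
  expect_true(all(diff(ph) >= 0))
  hp <- (Arg(analytic_signal(x)) * 180 / pi) %% 360
  interior <- ph > 15 & ph < 345 & abs(ph - 90) > 10 & abs(ph - 180) > 10 &
    abs(ph - 270) > 10
  dd <- abs(((ph - hp[idx] + 180) %% 360) - 180)
  expect_lt(max(dd[interior]), 2.5)
})

test_that("cycle selection applies duration, power and video criteria", {
  t <- seq_len(4 * fs) / fs
  x <- cos(2 * pi * 8 * t)
  cyc <- detect_candidate_cycles(x, fs)
  n <- nrow(cyc)
  theta_env <- rep(1, length(x))
  infra_env <- rep(0.1, length(x))
  sel <- select_cycles(cyc, theta_env, infra_env, behavior_times = t, fs = fs)
  expect_true(all(sel$accepted))
  # duration bound: squeeze the admissible range
  sel2 <- select_cycles(cyc, theta_env, infra_env, behavior_times = t,
                        fs = fs, dur_bounds = c(83, 100))
  expect_true(all(!sel2$accepted))
  expect_true(all(sel2$reason == "duration"))
  # power criterion at the midpoint
  infra_hi <- rep(2, length(x))
  sel3 <- select_cycles(cyc, theta_env, infra_hi, behavior_times = t, fs = fs)
  expect_true(all(sel3$reason == "power"))
  # no coincident video sample
  sel4 <- select_cycles(cyc, theta_env, infra_env,
                        behavior_times = numeric(0), fs = fs)
  expect_true(all(sel4$reason == "video"))
  # accepted + rejected partition candidates, reasons partition rejections
  expect_equal(sum(sel$accepted) + sum(!sel$accepted), n)
  expect_true(all(sel3$reason[!sel3$accepted] != ""))
})

test_that("snippets average a constant spectrogram to a constant matrix", {
  sp <- structure(list(amplitude = matrix(2.5, 38, 1000),
                       freqs = seq(15, 200, 5), fs = fs),
                  class = "spectrogram")
  cyc <- data.frame(cycle_id = 1, start_peak = 300, desc_flank = 330,
                    trough = 355, asc_flank = 380, end_peak = 410)
  sn <- build_cycle_snippet(sp, cyc)
  expect_equal(dim(sn), c(38, 36))
  expect_true(all(abs(sn - 2.5) < 1e-12))
})

test_that("a 100 ms cycle spreads its samples at up to 4 per phase bin", {
  set.seed(4)
  sp <- structure(list(amplitude = matrix(runif(38 * 1000), 38),
                       freqs = seq(15, 200, 5), fs = fs),
                  class = "spectrogram")
  cyc <- data.frame(cycle_id = 1, start_peak = 200, desc_flank = 225,
                    trough = 250, asc_flank = 275, end_peak = 300)
  idx <- 200:300
  ph <- waveform_phase(cyc, idx)
  bins <- pmin(pmax(ceiling(ph / 10), 1), 36)
  expect_lte(max(table(bins)), 4)
  expect_error(build_cycle_snippet(sp, transform(cyc, end_peak = 1400)),
               "outside")
})

test_that("an injected 80 Hz burst at phase 180 peaks at its snippet cell", {
  tt <- seq_len(2 * fs) / fs
  period <- 0.125
  cyct <- gammel:::theta_cycle_times(1.000, period, 1)
  sig <- gammel:::morlet_burst(tt, cyct$trough, 80, 1, 6)
  sp <- wavelet_amplitude(sig, fs)
  cyc <- data.frame(cycle_id = 1,
                    start_peak = round(cyct$t0 * fs),
                    desc_flank = round((cyct$t0 + cyct$t_decay / 2) * fs),
                    trough = round(cyct$trough * fs),
                    asc_flank = round((cyct$trough + cyct$t_rise / 2) * fs),
                    end_peak = round(cyct$t1 * fs))
  sn <- build_cycle_snippet(sp, cyc)
  am <- which(sn == max(sn), arr.ind = TRUE)
  expect_equal(attr(sn, "freqs")[am[1]], 80)
  expect_true(am[2] %in% c(18, 19))
})
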