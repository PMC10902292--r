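test_that("behavior track labels every sample with exactly one section", {
  beh <- generate_behavior(n_trials = 1, n_days = 1, seed = 0)
  expect_true(all(beh$section %in%
                    c("reward_RF", "target_arm", "other_RF", "other")))
  expect_false(anyNA(beh$section))
  expect_true(all(diff(beh$time) > 0))
  expect_true(all(beh$speed >= 0))
})

test_that("latency to reward decreases across training days", {
  beh <- generate_behavior(n_trials = 4, n_days = 10, seed = 3)
  lat <- latency_by_day(beh)
  expect_lt(mean(lat$latency[lat$day_index == 10]),
            mean(lat$latency[lat$day_index == 1]))
})

test_that("speed never exceeds the configured cap", {
  beh <- generate_behavior(n_trials = 2, n_days = 2, seed = 1,
                           speed_cap = 90)
  expect_lte(max(beh$speed), 90)
})

test_that("invalid maze geometry is rejected", {
  expect_error(maze_geometry(rf_length = 60, arm_length = 55), "overlaps")
  expect_error(maze_geometry(center_radius = -1), "invalid")
})

test_that("section modulation is the identity under an empty map", {
  bs <- burst_spec(freq_mean = 60)
  expect_identical(modulate_by_section(bs, "reward_RF", list()), bs)
})

test_that("section modulation shifts the mean frequency additively", {
  bs <- burst_spec(freq_mean = 60)
  map <- list(reward_RF = list(freq_shift = 20))
  expect_equal(modulate_by_section(bs, "reward_RF", map)$freq_mean, 80)
  expect_error(modulate_by_section(bs, "unknown_place", map), "unknown")
})

test_that("ground truth exports round-trip losslessly", {
  gt <- data.frame(channel = c(1L, 2L, 2L), cycle_index = c(1L, 1L, 2L),
                   time = c(0.1, 0.15, 0.3), freq = c(40, 80, 120),
                   phase = c(10, 180, 350), amplitude = c(1, 2, 0.5),
                   section = c("other", "target_arm", "reward_RF"),
                   speed = c(10, 20, 30))
  path <- tempfile(fileext = ".csv")
  export_ground_truth(gt, path)
  expect_equal(read.csv(path), gt)
  empty <- gt[0, ]
  export_ground_truth(empty, path)
  expect_equal(nrow(read.csv(path)), 0)
})

test_that("recording without bursts is theta plus noise only", {
  beh <- generate_behavior(n_trials = 1, n_days = 1, seed = 2)
  spec <- recording_spec(seed = 2, noise_sd = 0, bursts = list(),
                         theta_asym = 1)
  rec <- generate_recording(spec, beh, duration_s = 4)
  expect_equal(nrow(rec$ground_truth), 0)
  # fissure channel carries a unit-amplitude theta wave
  fis <- rec$samples[, spec$fissure_channel]
  expect_equal(max(abs(fis)), 1, tolerance = 1e-6)
  # phase inversion above the pyramidal layer
  ch_or <- which(spec$layer_of_channel == "or")[1]
  expect_lt(cor(rec$samples[, ch_or], fis), -0.99)
  # no energy outside theta: spectrum peak at the theta frequency
  P <- Mod(fft(fis - mean(fis)))^2
  fr <- (seq_along(fis) - 1) * 1000 / length(fis)
  expect_equal(fr[which.max(P[fr <= 500])], spec$theta_freq,
               tolerance = 0.3)
})

test_that("injected bursts are logged one record each with their draws", {
  beh <- generate_behavior(n_trials = 1, n_days = 1, seed = 4)
  lay <- rep("extra", 8); lay[4] <- "rad"; lay[6] <- "fissure"
  spec <- recording_spec(n_channels = 8, fissure_channel = 6, seed = 4,
                         noise_sd = 0, layer_of_channel = lay,
                         bursts = list(rad = burst_spec(
                           rate = 1, freq_mean = 80, freq_sd = 0,
                           phase_mean = 180, phase_sd = 0, amp_mean = 1,
                           amp_sd = 0, fixed_count = TRUE)))
  rec <- generate_recording(spec, beh, duration_s = 3)
  gt <- rec$ground_truth
  n_cycles <- sum(rec$cycles$t_end <= 3)
  expect_equal(nrow(gt), n_cycles)
  expect_true(all(gt$freq == 80))
  expect_true(all(gt$phase == 180))
  expect_true(all(gt$channel == 4))
  # burst centers sit at the cycle troughs (phase 180)
  expect_equal(gt$time, rec$cycles$t_trough[gt$cycle_index],
               tolerance = 1e-9)
})

test_that("recording demands behavior coverage", {
  beh <- generate_behavior(n_trials = 1, n_days = 1, seed = 5)
  spec <- recording_spec(seed = 5)
  expect_error(generate_recording(spec, beh,
                                  duration_s = max(beh$time) + 10),
               "duration")
})

test_that("theta-power depth profile puts the fissure where requested", {
  beh <- generate_behavior(n_trials = 1, n_days = 1, seed = 6)
  spec <- recording_spec(seed = 6, fissure_channel = 12, noise_sd = 0.01,
                         bursts = list())
  rec <- generate_recording(spec, beh, duration_s = 6)
  loc <- locate_fissure(rec$samples, rec$fs)
  expect_equal(loc$channel, 12)
  expect_equal(loc$position, 12, tolerance = 0.3)
})

test_that("multichannel binary+sidecar files round-trip", {
  beh <- generate_behavior(n_trials = 1, n_days = 1, seed = 7)
  spec <- recording_spec(n_channels = 6, fissure_channel = 4, seed = 7,
                         layer_of_channel = c("or", "pyr", "rad",
                                              "fissure", "DG", "extra"))
  rec <- generate_recording(spec, beh, duration_s = 2)
  prefix <- tempfile()
  write_lfp(rec, prefix)
  back <- read_lfp(prefix)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$layer, rec$layer)
})
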