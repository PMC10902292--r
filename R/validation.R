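#' Ground-truth validation recording for burst parameter recovery
#'
#' Builds the standard fixture used to validate the detection pipeline
#' against injected bursts: a 16-channel recording with a symmetric theta
#' carrier and two spatially isolated burst channels (a slow-gamma
#' "rad-like" channel 7 at 45 Hz, phase 315 degrees, and a medium-gamma
#' "l-m-like" channel 10 at 85 Hz, phase 180 degrees), exactly one
#' high-amplitude burst per cycle per channel, and low noise. The design
#' isolates detector accuracy: burst channels are spaced so CSD does not
#' duplicate bursts across detection channels, counts are deterministic so
#' bursts are well separated in time, and the carrier is symmetric because
#' band-limiting an asymmetric carrier to 4-12 Hz shifts waveform
#' landmarks by a few degrees (a property of the composite definition
#' quantified in the methods vignette, not of the detector).
#'
#' @param seed integer seed.
#' @param duration_s recording length in seconds (default 60).
#' @return list with \code{behavior}, \code{recording}, and
#'   \code{channels} (the two detection channels).
#' @export
validation_recording <- function(seed = 1, duration_s = 60) {
  behavior <- generate_behavior(seed = seed, n_trials = 6, n_days = 1)
  lay <- rep("extra", 16)
  lay[7] <- "rad"; lay[10] <- "l-m"; lay[12] <- "fissure"
  spec <- recording_spec(
    seed = seed, noise_sd = 0.01, theta_asym = 1, layer_of_channel = lay,
    bursts = list(
      rad = burst_spec(rate = 1, freq_mean = 45, freq_sd = 5,
                       phase_mean = 315, phase_sd = 30, amp_mean = 3,
                       amp_sd = 0.5, fixed_count = TRUE),
      `l-m` = burst_spec(rate = 1, freq_mean = 85, freq_sd = 10,
                         phase_mean = 180, phase_sd = 30, amp_mean = 3,
                         amp_sd = 0.5, fixed_count = TRUE)))
  list(behavior = behavior,
       recording = generate_recording(spec, behavior,
                                      duration_s = duration_s),
       channels = c(7L, 10L))
}

#' Burst recovery rates of the detection pipeline
#'
#' Runs [extract_gamma_elements()] on a ground-truth recording and
#' reports the fraction of injected bursts recovered within the stated
#' frequency and phase tolerances. Only analyzable bursts are scored:
#' those inside the pipeline's edge margins and separated from the nearest
#' same-channel burst by at least \code{min_gap_s} (overlapping wavelet
#' responses cannot be attributed to a single burst).
#'
#' @param fixture output of [validation_recording()].
#' @param n_realizations EEMD ensemble size (default 100).
#' @param freq_tol,phase_tol recovery tolerances (2.5 Hz, 5 degrees: half
#'   a spectrogram cell).
#' @param min_gap_s separation defining well-isolated bursts (default
#'   0.06 s).
#' @param edge_s scored time range margin (default 0.7 s).
#' @return list with \code{freq_rate}, \code{phase_rate}, \code{both_rate},
#'   \code{matched_rate}, \code{n_bursts}, \code{errors} (per-burst
#'   data.frame), \code{elements}.
#' @export
burst_recovery <- function(fixture, n_realizations = 100, freq_tol = 2.5,
                           phase_tol = 5, min_gap_s = 0.06, edge_s = 0.7) {
  rec <- fixture$recording
  els <- extract_gamma_elements(rec, fixture$behavior,
                                channels = fixture$channels,
                                n_realizations = n_realizations)
  gt <- rec$ground_truth
  dur <- nrow(rec$samples) / rec$fs
  gt <- gt[gt$time > edge_s & gt$time < dur - edge_s, ]
  gap <- vapply(seq_len(nrow(gt)), function(i)
    min(abs(gt$time[i] - gt$time[-i][gt$channel[-i] == gt$channel[i]])),
    numeric(1))
  gt <- gt[gap >= min_gap_s, ]
  m <- match_ground_truth(els, gt)
  ok <- m$matched & abs(m$freq_err) <= freq_tol & abs(m$phase_err) <= phase_tol
  list(freq_rate = mean(abs(m$freq_err) <= freq_tol, na.rm = TRUE),
       phase_rate = mean(abs(m$phase_err) <= phase_tol, na.rm = TRUE),
       both_rate = mean(ok),
       matched_rate = mean(m$matched),
       n_bursts = nrow(gt),
       errors = m, elements = els)
}

#' Decoding validation pair: unmodulated and section-modulated recordings
#'
#' Builds two recordings that differ only in the section modulation map:
#' one with no section dependence (the decoding null) and one whose burst
#' mean frequencies shift strongly with the maze section. Used to verify
#' that cross-validated decoding sits at chance on the null and above
#' chance under modulation.
#'
#' Like the in-vivo analysis, decoding is evaluated per channel: a single
#' rad-like burst channel carries the section signal, so the null cannot
#' pick up channel-mixture fluctuations across sections. The burst rate
#' (3 per cycle) keeps most of the four-element-per-cycle budget occupied
#' by genuine oscillatory events, as in real recordings, rather than by
#' residual-noise patches.
#'
#' @param seed integer seed.
#' @param duration_s recording length (default 90 s, covering several
#'   trials so every maze section contributes enough theta cycles).
#' @param freq_shifts named list of per-section frequency shifts in Hz for
#'   the modulated recording.
#' @return list with \code{behavior} and recordings \code{null},
#'   \code{modulated}; \code{channels} as in [validation_recording()].
#' @export
decoding_fixture <- function(seed = 2, duration_s = 90,
                             freq_shifts = list(reward_RF = 45,
                                                target_arm = 15,
                                                other_RF = -10,
                                                other = 0)) {
  behavior <- generate_behavior(seed = seed, n_trials = 6, n_days = 1)
  lay <- rep("extra", 16)
  lay[7] <- "rad"; lay[12] <- "fissure"
  base_bursts <- list(
    rad = burst_spec(rate = 3, freq_mean = 70, freq_sd = 10,
                     phase_mean = 315, phase_sd = 40, amp_mean = 3,
                     amp_sd = 0.5))
  mk <- function(map, seed_off) {
    spec <- recording_spec(seed = child_seed(seed, seed_off),
                           noise_sd = 0.01, theta_asym = 1,
                           layer_of_channel = lay, bursts = base_bursts,
                           modulation_map = map)
    generate_recording(spec, behavior, duration_s = duration_s)
  }
  mod_map <- lapply(freq_shifts, function(s) list(freq_shift = s))
  list(behavior = behavior,
       null = mk(list(), 101),
       modulated = mk(mod_map, 102),
       channels = 7L)
}

#' Reduced-scale working points for the regime contrast
#'
#' Two frozen parameter sets used to check the qualitative regime
#' ordering at desk scale (n = 500 neurons, dt = 0.01 ms, 20 s): the
#' "fringe" point is the default working point (K = 20, weak E-to-I
#' coupling) producing broadband, weakly synchronized transient gamma;
#' the "synchronous" point (K = 320, g0_IE = 0.5) sits above the
#' transition to collective oscillation, with narrower-band rhythms and
#' larger mean-membrane-potential fluctuations.
#'
#' @param n network size (default 500).
#' @param dt Euler step in ms (default 0.01).
#' @param seed integer seed.
#' @return named list of two [network_params()]: \code{fringe},
#'   \code{synchronous}.
#' @export
regime_points <- function(n = 500, dt = 0.01, seed = 7) {
  list(fringe = network_params(n = n, dt = dt, seed = seed),
       synchronous = network_params(n = n, K = 320, g0_IE = 0.5, dt = dt,
                                    seed = seed))
}
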