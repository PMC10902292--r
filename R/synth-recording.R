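#' Per-layer gamma burst distribution
#'
#' Parameterizes the distribution of transient gamma bursts injected into a
#' synthetic recording: Poisson count per theta cycle, Gaussian frequency
#' (truncated to 30-250 Hz), wrapped-Gaussian theta phase, Gaussian
#' amplitude (truncated positive), and the cycle count of the
#' Gaussian-windowed cosine waveform.
#'
#' @param rate expected bursts per theta cycle.
#' @param freq_mean,freq_sd burst frequency distribution in Hz.
#' @param phase_mean,phase_sd theta phase of the burst center in degrees.
#' @param amp_mean,amp_sd burst amplitude distribution (signal units).
#' @param n_cycles cycles under the Gaussian envelope (default 6).
#' @param fixed_count if TRUE the burst count per cycle is exactly
#'   \code{round(rate)} instead of Poisson-distributed; used by validation
#'   fixtures that require exactly one burst per cycle.
#' @return list of class \code{burst_spec}.
#' @export
burst_spec <- function(rate = 1, freq_mean = 60, freq_sd = 10,
                       phase_mean = 180, phase_sd = 40,
                       amp_mean = 1, amp_sd = 0.25, n_cycles = 6,
                       fixed_count = FALSE) {
  if (freq_mean < 30 || freq_mean > 250)
    stop("burst_spec: frequency outside 30-250 Hz")
  structure(list(rate = rate, freq_mean = freq_mean, freq_sd = freq_sd,
                 phase_mean = phase_mean, phase_sd = phase_sd,
                 amp_mean = amp_mean, amp_sd = amp_sd, n_cycles = n_cycles,
                 fixed_count = fixed_count),
            class = "burst_spec")
}

#' Apply a section-dependent modulation to a burst distribution
#'
#' The modulation map gives, per maze section, additive shifts of the mean
#' frequency and phase, and multiplicative scalings of the amplitude mean
#' and burst rate. An empty map is the identity.
#'
#' @param spec a [burst_spec()].
#' @param section section label.
#' @param modulation_map named list: \code{section -> list(freq_shift,
#'   phase_shift, amp_scale, rate_scale)} (missing entries default to the
#'   identity).
#' @return modulated \code{burst_spec}.
#' @export
modulate_by_section <- function(spec, section, modulation_map = list()) {
  stopifnot(inherits(spec, "burst_spec"))
  if (length(modulation_map) == 0) return(spec)
  if (!section %in% names(modulation_map))
    stop("modulate_by_section: unknown section '", section, "'")
  m <- modulation_map[[section]]
  spec$freq_mean <- spec$freq_mean + (m$freq_shift %||% 0)
  spec$phase_mean <- (spec$phase_mean + (m$phase_shift %||% 0)) %% 360
  spec$amp_mean <- spec$amp_mean * (m$amp_scale %||% 1)
  spec$rate <- spec$rate * (m$rate_scale %||% 1)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of a synthetic multichannel recording
#'
#' Defaults emulate a 16-channel laminar probe at 50 um spacing crossing
#' CA1 into the dentate gyrus, with the theta-power depth profile peaking
#' at the fissure channel and a 180 degree theta phase inversion above the
#' pyramidal layer.
#'
#' @param n_channels number of channels (>= 3).
#' @param spacing_mm inter-channel spacing in mm (default 0.05).
#' @param layer_of_channel character vector of layer labels per channel;
#'   default assigns or, pyr, rad, l-m, fissure, DG along the probe.
#' @param fissure_channel channel of peak theta power (default 12).
#' @param theta_freq,theta_amp,theta_asym theta frequency (Hz), amplitude
#'   at the fissure, and rise/decay asymmetry ratio.
#' @param theta_sigma width (in channels) of the Gaussian theta-power
#'   depth profile.
#' @param bursts named list \code{layer -> burst_spec}; layers without an
#'   entry receive no bursts.
#' @param modulation_map section modulation map (see
#'   [modulate_by_section()]); empty for unmodulated recordings.
#' @param noise_sd white noise standard deviation (signal units).
#' @param seed integer seed.
#' @return list of class \code{recording_spec}.
#' @export
recording_spec <- function(n_channels = 16, spacing_mm = 0.05,
                           layer_of_channel = NULL, fissure_channel = 12,
                           theta_freq = 8, theta_amp = 1, theta_asym = 1.25,
                           theta_sigma = 3,
                           bursts = list(rad = burst_spec(freq_mean = 45,
                                                          phase_mean = 315),
                                         `l-m` = burst_spec(freq_mean = 85,
                                                            phase_mean = 180)),
                           modulation_map = list(), noise_sd = 0.05,
                           seed = 0) {
  if (n_channels < 3) stop("recording_spec: CSD needs at least 3 channels")
  if (is.null(layer_of_channel)) {
    frac <- (seq_len(n_channels) - 1) / (fissure_channel - 1)
    layer_of_channel <- cut(frac, c(-Inf, .15, .3, .75, .97, 1.03, Inf),
                            labels = c("or", "pyr", "rad", "l-m", "fissure",
                                       "DG"))
    layer_of_channel <- as.character(layer_of_channel)
  }
  stopifnot(length(layer_of_channel) == n_channels)
  for (b in bursts)
    if (b$freq_mean < 30 || b$freq_mean > 250)
      stop("recording_spec: burst frequency outside 30-250 Hz")
  structure(list(n_channels = n_channels, spacing_mm = spacing_mm,
                 layer_of_channel = layer_of_channel,
                 fissure_channel = fissure_channel, theta_freq = theta_freq,
                 theta_amp = theta_amp, theta_asym = theta_asym,
                 theta_sigma = theta_sigma, bursts = bursts,
                 modulation_map = modulation_map, noise_sd = noise_sd,
                 seed = seed),
            class = "recording_spec")
}

# closed-form landmarks of a generated theta cycle: start peak at t0,
# trough at t0 + T_decay, end peak at t0 + T. asym = rise/decay ratio.
theta_cycle_times <- function(t0, period, asym) {
  t_decay <- period / (1 + asym)
  list(t0 = t0, trough = t0 + t_decay, t1 = t0 + period,
       t_decay = t_decay, t_rise = period - t_decay)
}

# time-warped cosine evaluated at times t inside one cycle
theta_cycle_wave <- function(t, cyc) {
  s <- ifelse(t < cyc$trough,
              (t - cyc$t0) / cyc$t_decay,
              1 + (t - cyc$trough) / cyc$t_rise)
  cos(pi * s)
}

# time at which the waveform phase (quadrant convention) equals phi degrees
theta_time_at_phase <- function(phi, cyc) {
  phi <- phi %% 360
  ifelse(phi < 90, cyc$t0 + phi / 90 * cyc$t_decay / 2,
  ifelse(phi < 180, cyc$t0 + cyc$t_decay / 2 + (phi - 90) / 90 * cyc$t_decay / 2,
  ifelse(phi < 270, cyc$trough + (phi - 180) / 90 * cyc$t_rise / 2,
         cyc$trough + cyc$t_rise / 2 + (phi - 270) / 90 * cyc$t_rise / 2)))
}

#' Generate a synthetic multichannel LFP with known gamma bursts
#'
#' Builds a 1 kHz recording as depth-profiled asymmetric theta (peak power
#' at the fissure channel, phase-inverted above the pyramidal layer), plus
#' Gaussian-windowed cosine gamma bursts drawn per theta cycle from the
#' per-layer burst distributions (modulated by the maze section occupied at
#' the cycle time), plus white noise. Every injected burst is logged in the
#' returned ground truth.
#'
#' @param spec a [recording_spec()].
#' @param behavior a behavior track from [generate_behavior()]; must cover
#'   \code{duration_s}.
#' @param duration_s recording duration in seconds (default: full behavior).
#' @param fs sampling rate in Hz (default 1000).
#' @return list of class \code{multichannel_lfp} with \code{samples}
#'   (time x channel), \code{fs}, \code{depth_mm}, \code{layer},
#'   \code{ground_truth} (one row per injected burst: channel, cycle_index,
#'   time, freq, phase, amplitude, section), and \code{cycles} (true cycle
#'   start/trough/end times).
#' @export
generate_recording <- function(spec, behavior, duration_s = NULL, fs = 1000) {
  stopifnot(inherits(spec, "recording_spec"))
  if (is.null(duration_s)) duration_s <- floor(max(behavior$time))
  if (max(behavior$time) < duration_s)
    stop("generate_recording: behavior does not cover requested duration")
  set.seed(child_seed(spec$seed, 2))
  n <- round(duration_s * fs)
  tt <- seq_len(n) / fs
  nc <- spec$n_channels

  # theta cycle grid
  period <- 1 / spec$theta_freq
  starts <- seq(0, duration_s, by = period)
  cycles <- lapply(starts, theta_cycle_times, period = period,
                   asym = spec$theta_asym)

  # depth-profiled theta with phase inversion above pyr
  prof <- spec$theta_amp *
    exp(-((seq_len(nc) - spec$fissure_channel)^2) / (2 * spec$theta_sigma^2))
  flip <- ifelse(spec$layer_of_channel %in% c("or", "pyr"), -1, 1)
  wave <- numeric(n)
  for (cyc in cycles) {
    i <- which(tt >= cyc$t0 & tt < cyc$t1)
    if (length(i)) wave[i] <- theta_cycle_wave(tt[i], cyc)
  }
  samples <- outer(wave, prof * flip)

  # per-cycle, per-layer burst injection
  section_at <- function(time) {
    i <- findInterval(time, behavior$time)
    behavior$section[max(i, 1)]
  }
  speed_at <- function(time) {
    i <- findInterval(time, behavior$time)
    behavior$speed[max(i, 1)]
  }
  gt <- list()
  for (ci in seq_along(cycles)) {
    cyc <- cycles[[ci]]
    if (cyc$t1 > duration_s) next
    mid <- (cyc$t0 + cyc$t1) / 2
    sect <- section_at(mid)
    for (layer in names(spec$bursts)) {
      chs <- which(spec$layer_of_channel == layer)
      if (!length(chs)) next
      bs <- spec$bursts[[layer]]
      if (length(spec$modulation_map))
        bs <- tryCatch(modulate_by_section(bs, sect, spec$modulation_map),
                       error = function(e) bs)
      for (ch in chs) {
        nb <- if (isTRUE(bs$fixed_count)) round(bs$rate) else
          stats::rpois(1, bs$rate)
        if (nb == 0) next
        for (b in seq_len(nb)) {
          f <- min(max(rnorm(1, bs$freq_mean, bs$freq_sd), 30), 250)
          ph <- (rnorm(1, bs$phase_mean, bs$phase_sd)) %% 360
          a <- abs(rnorm(1, bs$amp_mean, bs$amp_sd))
          tc <- theta_time_at_phase(ph, cyc)
          sigma <- bs$n_cycles / (2 * pi * f)
          win <- which(tt > tc - 4 * sigma & tt < tc + 4 * sigma)
          if (!length(win)) next
          samples[win, ch] <- samples[win, ch] +
            morlet_burst(tt[win], tc, f, a, bs$n_cycles)
          gt[[length(gt) + 1]] <- data.frame(
            channel = ch, cycle_index = ci, time = tc, freq = f, phase = ph,
            amplitude = a, section = sect, speed = speed_at(mid))
        }
      }
    }
  }
  if (spec$noise_sd > 0)
    samples <- samples + matrix(rnorm(n * nc, 0, spec$noise_sd), n, nc)

  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(channel = integer(), cycle_index = integer(), time = numeric(),
               freq = numeric(), phase = numeric(), amplitude = numeric(),
               section = character(), speed = numeric())
  cyc_df <- data.frame(
    cycle_index = seq_along(cycles),
    t_start = vapply(cycles, `[[`, numeric(1), "t0"),
    t_trough = vapply(cycles, `[[`, numeric(1), "trough"),
    t_end = vapply(cycles, `[[`, numeric(1), "t1"))
  structure(list(samples = samples, fs = fs,
                 depth_mm = (seq_len(nc) - 1) * spec$spacing_mm,
                 layer = spec$layer_of_channel, spacing_mm = spec$spacing_mm,
                 fissure_channel = spec$fissure_channel,
                 ground_truth = gt, cycles = cyc_df, spec = spec),
            class = "multichannel_lfp")
}

#' Write ground truth to CSV
#'
#' One row per injected burst; round-trips losslessly through
#' \code{read.csv}.
#'
#' @param gt ground-truth data.frame from [generate_recording()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_ground_truth <- function(gt, path) {
  write.csv(gt, path, row.names = FALSE)
  invisible(path)
}

#' Write a multichannel LFP to disk
#'
#' Flat little-endian binary of channel-major float64 samples plus a JSON
#' sidecar holding the rate, channel count, depths and layer labels.
#'
#' @param lfp a \code{multichannel_lfp}.
#' @param prefix path prefix; writes \code{<prefix>.bin} and
#'   \code{<prefix>.json}.
#' @return the prefix, invisibly.
#' @export
write_lfp <- function(lfp, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(lfp$samples), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(fs = lfp$fs, n_channels = ncol(lfp$samples),
         n_samples = nrow(lfp$samples), depth_mm = lfp$depth_mm,
         layer = lfp$layer, spacing_mm = lfp$spacing_mm),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a multichannel LFP written by [write_lfp()]
#'
#' @param prefix path prefix used at write time.
#' @return a \code{multichannel_lfp} (without ground truth).
#' @export
read_lfp <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_samples * meta$n_channels,
               size = 8, endian = "little")
  structure(list(samples = matrix(x, meta$n_samples, meta$n_channels),
                 fs = meta$fs, depth_mm = meta$depth_mm, layer = meta$layer,
                 spacing_mm = meta$spacing_mm),
            class = "multichannel_lfp")
}
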