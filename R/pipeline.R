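#' Extract gamma elements from a multichannel recording
#'
#' Runs the full detection pipeline on one recording: EEMD decomposition of
#' the fissure channel into theta and infra-theta composites, theta cycle
#' segmentation and selection, per-channel gamma composites, CSD, Morlet
#' spectrogram, per-cycle snippets, threshold-scan patch detection with
#' cross-cycle boundary resolution, and 6-feature parameterization. Maze
#' section and speed are joined from the behavior track at each cycle
#' midpoint.
#'
#' @param recording a \code{multichannel_lfp} (from [generate_recording()]
#'   or [read_lfp()]).
#' @param behavior a behavior track covering the recording.
#' @param channels channels at which to detect elements (must be interior
#'   channels); default: every interior channel whose layer is not
#'   \code{fissure}.
#' @param n_realizations EEMD ensemble size used for the decompositions
#'   (default 100; see the methods vignette for the scale rationale).
#' @param fissure_channel override for the theta reference channel;
#'   default: the recording's \code{fissure_channel} if present, otherwise
#'   the [locate_fissure()] estimate.
#' @param max_per_cycle maximum elements per theta cycle (default 4).
#' @param trial_index trial label attached to the output rows (default 1);
#'   used by [compile_element_table()] for per-trial filtering.
#' @param edge_margin_s cycles starting or ending within this margin of
#'   the recording edges are dropped (default 0.5 s); sifting envelopes
#'   and wavelet kernels are unreliable there.
#' @param verbose print progress.
#' @return data.frame with one row per element: the six features, plus
#'   \code{channel}, \code{layer}, \code{trial}, \code{cycle_id},
#'   \code{t_center}, \code{section}, \code{speed}.
#' @export
extract_gamma_elements <- function(recording, behavior, channels = NULL,
                                   n_realizations = 100,
                                   fissure_channel = NULL,
                                   max_per_cycle = 4, trial_index = 1,
                                   edge_margin_s = 0.5, verbose = FALSE) {
  fs <- recording$fs
  samples <- recording$samples
  nc <- ncol(samples)
  if (is.null(fissure_channel))
    fissure_channel <- recording$fissure_channel %||%
      locate_fissure(samples, fs)$channel
  if (is.null(channels)) {
    channels <- setdiff(2:(nc - 1), fissure_channel)
    channels <- channels[recording$layer[channels] != "fissure"]
  }
  stopifnot(all(channels > 1 & channels < nc))

  decomp <- list()
  get_imfs <- function(ch) {
    key <- as.character(ch)
    if (is.null(decomp[[key]])) {
      if (verbose) message("decomposing channel ", ch)
      decomp[[key]] <<- decompose_signal(samples[, ch], fs,
                                         n_realizations = n_realizations)
    }
    decomp[[key]]
  }

  imf_fis <- get_imfs(fissure_channel)
  theta <- band_composite(imf_fis, "theta")
  infra <- band_composite(imf_fis, "infra")
  cand <- detect_candidate_cycles(theta, fs)
  if (nrow(cand) == 0) return(empty_element_table())
  cand <- select_cycles(cand, Mod(analytic_signal(theta)),
                        Mod(analytic_signal(infra)),
                        behavior_times = behavior$time, fs = fs)
  margin <- round(edge_margin_s * fs)
  acc <- which(cand$accepted &
                 cand$start_peak > margin &
                 cand$end_peak < nrow(samples) - margin)
  if (!length(acc)) return(empty_element_table())

  out <- list()
  for (ch in channels) {
    gl <- vapply(c(ch - 1, ch, ch + 1),
                 function(k) band_composite(get_imfs(k), "gamma"),
                 numeric(nrow(samples)))
    csd <- (-gl[, 1] + 2 * gl[, 2] - gl[, 3]) / recording$spacing_mm^2
    spec <- wavelet_amplitude(csd, fs)
    snippets <- vector("list", nrow(cand))
    for (k in seq_len(nrow(cand)))
      snippets[[k]] <- build_cycle_snippet(spec, cand[k, ])
    for (k in acc) {
      nb <- list(
        prev = if (k > 1 && cand$end_peak[k - 1] == cand$start_peak[k])
          snippets[[k - 1]],
        next_ = if (k < nrow(cand) && cand$start_peak[k + 1] == cand$end_peak[k])
          snippets[[k + 1]])
      patches <- detect_patches(snippets[[k]], neighbors = nb,
                                max_count = max_per_cycle)
      if (!length(patches)) next
      cyc <- cand[k, ]
      els <- do.call(rbind, lapply(patches, characterize_element,
                                   cycle = cyc, freqs = spec$freqs))
      mid_t <- (cyc$start_peak + cyc$end_peak) / 2 / fs
      bi <- max(findInterval(mid_t, behavior$time), 1)
      els$channel <- ch
      els$layer <- recording$layer[ch]
      els$trial <- trial_index
      els$t_center <- vapply(els$gamma_phase, function(p)
        approx(c(0, 90, 180, 270, 360),
               c(cyc$start_peak, cyc$desc_flank, cyc$trough, cyc$asc_flank,
                 cyc$end_peak), xout = p %% 360)$y / fs, numeric(1))
      els$section <- behavior$section[bi]
      els$speed <- behavior$speed[bi]
      out[[length(out) + 1]] <- els
    }
  }
  if (!length(out)) return(empty_element_table())
  res <- do.call(rbind, out)
  attr(res, "cycles") <- cand
  res
}

empty_element_table <- function() {
  data.frame(gamma_amplitude = numeric(), gamma_frequency = numeric(),
             gamma_phase = numeric(), theta_amplitude = numeric(),
             theta_frequency = numeric(), theta_asymmetry = numeric(),
             cycle_id = integer(), channel = integer(), layer = character(),
             trial = integer(), t_center = numeric(), section = character(),
             speed = numeric())
}

#' Compile and filter the element table
#'
#' Concatenates per-trial element tables, removes the top and bottom 1% of
#' gamma amplitudes within each trial-by-channel group, and drops elements
#' from cycles with implausibly large running speed.
#'
#' @param elements a data.frame from [extract_gamma_elements()] or a list
#'   of them (one per trial/recording).
#' @param amplitude_trim tail probability trimmed at each end (default
#'   0.01).
#' @param speed_max speed exclusion threshold in cm/s (default 100).
#' @return filtered element table (class \code{element_table}).
#' @export
compile_element_table <- function(elements, amplitude_trim = 0.01,
                                  speed_max = 100) {
  if (is.data.frame(elements)) elements <- list(elements)
  tab <- do.call(rbind, elements)
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- empty_element_table()
    class(tab) <- c("element_table", "data.frame")
    return(tab)
  }
  keep <- rep(TRUE, nrow(tab))
  grp <- interaction(tab$trial, tab$channel, drop = TRUE)
  for (g in levels(grp)) {
    i <- which(grp == g)
    q <- quantile(tab$gamma_amplitude[i],
                  c(amplitude_trim, 1 - amplitude_trim), names = FALSE)
    keep[i] <- tab$gamma_amplitude[i] > q[1] & tab$gamma_amplitude[i] < q[2]
  }
  keep <- keep & tab$speed <= speed_max
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("element_table", "data.frame")
  out
}

#' Match detected elements to injected ground-truth bursts
#'
#' For each ground-truth burst, the detected elements on the same channel
#' whose center time falls within the matching window are considered;
#' low-amplitude detections (below half the strongest candidate, typically
#' residual-noise patches) are discarded and the remaining element nearest
#' in time is taken as the recovered element. Frequency and (circular)
#' phase errors are reported.
#'
#' @param elements element table from [extract_gamma_elements()].
#' @param ground_truth ground-truth table from [generate_recording()].
#' @param window_s temporal matching window in seconds (default 0.07,
#'   about half a theta period).
#' @return data.frame with one row per ground-truth burst: \code{matched},
#'   \code{freq_err} (Hz), \code{phase_err} (degrees, in [-180, 180]).
#' @export
match_ground_truth <- function(elements, ground_truth, window_s = 0.07) {
  out <- data.frame(matched = logical(nrow(ground_truth)),
                    freq_err = NA_real_, phase_err = NA_real_)
  for (i in seq_len(nrow(ground_truth))) {
    g <- ground_truth[i, ]
    cand <- elements[elements$channel == g$channel &
                       abs(elements$t_center - g$time) < window_s, ]
    if (!nrow(cand)) next
    cand <- cand[cand$gamma_amplitude >=
                   0.5 * max(cand$gamma_amplitude), , drop = FALSE]
    j <- which.min(abs(cand$t_center - g$time))
    out$matched[i] <- TRUE
    out$freq_err[i] <- cand$gamma_frequency[j] - g$freq
    out$phase_err[i] <- ((cand$gamma_phase[j] - g$phase + 180) %% 360) - 180
  }
  out
}
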