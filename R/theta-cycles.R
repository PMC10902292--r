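#' Segment a theta composite into candidate cycles
#'
#' Local maxima of the theta composite (minimum inter-peak distance 80 ms,
#' just below the shortest admissible cycle) delimit candidate cycles; the
#' trough is the minimum between consecutive peaks and the flanks are the
#' half-amplitude crossings between the trough and each surrounding peak.
#' Derived per-cycle features: duration (ms), frequency (1/duration),
#' amplitude (mean trough-to-adjacent-peak voltage difference) and
#' asymmetry (rise/decay duration ratio, trough-to-end over start-to-trough).
#'
#' @param theta theta composite signal (fissure channel).
#' @param fs sampling rate in Hz (default 1000).
#' @param min_peak_dist_ms minimum inter-peak distance (default 80 ms).
#' @return data.frame of class \code{theta_cycles}, one row per candidate
#'   cycle: \code{cycle_id}, landmark sample indices (\code{start_peak},
#'   \code{desc_flank}, \code{trough}, \code{asc_flank}, \code{end_peak}),
#'   \code{duration_ms}, \code{amplitude}, \code{frequency},
#'   \code{asymmetry}. Empty when fewer than two peaks exist.
#' @export
detect_candidate_cycles <- function(theta, fs = 1000, min_peak_dist_ms = 80) {
  peaks <- find_peaks(theta, round(min_peak_dist_ms * fs / 1000))
  empty <- data.frame(cycle_id = integer(), start_peak = integer(),
                      desc_flank = integer(), trough = integer(),
                      asc_flank = integer(), end_peak = integer(),
                      duration_ms = numeric(), amplitude = numeric(),
                      frequency = numeric(), asymmetry = numeric())
  class(empty) <- c("theta_cycles", "data.frame")
  if (length(peaks) < 2) return(empty)
  rows <- vector("list", length(peaks) - 1)
  for (k in seq_len(length(peaks) - 1)) {
    p0 <- peaks[k]; p1 <- peaks[k + 1]
    seg <- theta[p0:p1]
    tr <- p0 + which.min(seg) - 1
    if (tr <= p0 || tr >= p1) next
    half_desc <- (theta[p0] + theta[tr]) / 2
    half_asc <- (theta[p1] + theta[tr]) / 2
    # first crossing below half amplitude going down, last going up
    df <- p0 + which(theta[p0:tr] <= half_desc)[1] - 1
    af_rel <- which(theta[tr:p1] <= half_asc)
    af <- tr + af_rel[length(af_rel)] - 1
    if (is.na(df) || !length(af_rel)) next
    if (!(p0 < df && df < tr && tr < af && af < p1)) next
    dur <- (p1 - p0) / fs * 1000
    rows[[k]] <- data.frame(
      cycle_id = k, start_peak = p0, desc_flank = df, trough = tr,
      asc_flank = af, end_peak = p1, duration_ms = dur,
      amplitude = mean(c(theta[p0] - theta[tr], theta[p1] - theta[tr])),
      frequency = 1000 / dur,
      asymmetry = (p1 - tr) / (tr - p0))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out$cycle_id <- seq_len(nrow(out))
  class(out) <- c("theta_cycles", "data.frame")
  out
}

# strict local maxima with a minimum separation, strongest-first pruning
find_peaks <- function(x, min_dist) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (!length(cand)) return(integer())
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  for (i in ord) {
    lo <- max(1, i - min_dist); hi <- min(n, i + min_dist)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  sort(which(keep))
}

#' Waveform-based theta phase within a cycle
#'
#' Piecewise-linear phase across the four quadrants delimited by the cycle
#' landmarks: start peak (0), descending flank (90), trough (180),
#' ascending flank (270), end peak (360).
#'
#' @param cycle one row of a \code{theta_cycles} data.frame.
#' @param t sample index (or vector of indices) inside the cycle.
#' @return phase in degrees, in [0, 360].
#' @export
waveform_phase <- function(cycle, t) {
  if (any(t < cycle$start_peak | t > cycle$end_peak))
    stop("waveform_phase: sample outside the cycle")
  lm <- c(cycle$start_peak, cycle$desc_flank, cycle$trough,
          cycle$asc_flank, cycle$end_peak)
  approx(lm, c(0, 90, 180, 270, 360), xout = t)$y
}

#' Select theta cycles for analysis
#'
#' A candidate cycle is accepted iff (i) its duration lies in
#' [\code{dur_bounds}] ms, (ii) the theta-composite envelope exceeds the
#' infra-theta (1-4 Hz) composite envelope at the cycle start, mid and end
#' points, and (iii) at least one behavior sample falls within the cycle.
#' The rejection reason (first failed criterion) is recorded.
#'
#' @param cycles candidate cycles from [detect_candidate_cycles()].
#' @param theta_env,infra_env amplitude envelopes (analytic-signal modulus)
#'   of the theta and infra-theta composites.
#' @param behavior_times times (s) of behavior samples; \code{NULL} skips
#'   the video criterion.
#' @param fs sampling rate in Hz.
#' @param dur_bounds admissible duration range in ms (default c(83, 250)).
#' @param mid \code{"time"} (temporal midpoint, default) or \code{"trough"}
#'   for the mid-cycle power check.
#' @return \code{cycles} with added \code{accepted} (logical) and
#'   \code{reason} (\code{""}, \code{"duration"}, \code{"power"},
#'   \code{"video"}).
#' @export
select_cycles <- function(cycles, theta_env, infra_env, behavior_times = NULL,
                          fs = 1000, dur_bounds = c(83, 250),
                          mid = c("time", "trough")) {
  mid <- match.arg(mid)
  n <- nrow(cycles)
  accepted <- rep(TRUE, n)
  reason <- rep("", n)
  for (k in seq_len(n)) {
    cy <- cycles[k, ]
    if (cy$duration_ms < dur_bounds[1] || cy$duration_ms > dur_bounds[2]) {
      accepted[k] <- FALSE; reason[k] <- "duration"; next
    }
    m <- if (mid == "time") round((cy$start_peak + cy$end_peak) / 2) else cy$trough
    pts <- c(cy$start_peak, m, cy$end_peak)
    if (!all(theta_env[pts] > infra_env[pts])) {
      accepted[k] <- FALSE; reason[k] <- "power"; next
    }
    if (!is.null(behavior_times)) {
      t0 <- cy$start_peak / fs; t1 <- cy$end_peak / fs
      if (!any(behavior_times >= t0 & behavior_times <= t1)) {
        accepted[k] <- FALSE; reason[k] <- "video"
      }
    }
  }
  cycles$accepted <- accepted
  cycles$reason <- reason
  cycles
}

#' Per-cycle spectrogram snippet
#'
#' Averages the spectrogram amplitude of each frequency row within 10
#' degree bins of the waveform phase, yielding the 38 x 36
#' frequency-by-phase matrix that patch detection operates on. Empty phase
#' bins are filled by linear interpolation across phase (circular at the
#' edges). Phase bin \code{k} covers ((k-1)*10, k*10] degrees.
#'
#' @param spec a \code{spectrogram} from [wavelet_amplitude()].
#' @param cycle one row of a \code{theta_cycles} data.frame.
#' @param n_bins number of phase bins (default 36).
#' @return matrix (length(freqs) x n_bins) with attributes \code{freqs} and
#'   \code{cycle_id}.
#' @export
build_cycle_snippet <- function(spec, cycle, n_bins = 36) {
  stopifnot(inherits(spec, "spectrogram"))
  idx <- cycle$start_peak:cycle$end_peak
  if (cycle$start_peak < 1 || cycle$end_peak > ncol(spec$amplitude))
    stop("build_cycle_snippet: cycle outside the spectrogram")
  ph <- waveform_phase(cycle, idx)
  bin <- pmin(pmax(ceiling(ph / (360 / n_bins)), 1), n_bins)
  amp <- spec$amplitude[, idx, drop = FALSE]
  snip <- matrix(NA_real_, nrow(amp), n_bins)
  for (b in unique(bin))
    snip[, b] <- rowMeans(amp[, bin == b, drop = FALSE])
  # interpolate empty bins across phase (wrap at the edges)
  empty <- which(colSums(!is.na(snip)) == 0)
  if (length(empty)) {
    filled <- setdiff(seq_len(n_bins), empty)
    for (r in seq_len(nrow(snip))) {
      y <- snip[r, filled]
      snip[r, empty] <- approx(c(filled - n_bins, filled, filled + n_bins),
                               rep(y, 3), xout = empty)$y
    }
  }
  attr(snip, "freqs") <- spec$freqs
  attr(snip, "cycle_id") <- cycle$cycle_id
  snip
}
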