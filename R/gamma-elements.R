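#' Parameterize a gamma patch as a gamma element
#'
#' The element amplitude is the mean amplitude over the patch cells; the
#' frequency and phase are the amplitude-weighted means of the cell row
#' frequencies and phase-bin centers (circular for phase). The three theta
#' features (amplitude, frequency, asymmetry) are copied from the host
#' cycle.
#'
#' @param patch one patch from [detect_patches()].
#' @param cycle one row of a \code{theta_cycles} data.frame.
#' @param freqs row frequencies in Hz (default \code{seq(15, 200, 5)}).
#' @param n_bins phase bins per cycle (default 36).
#' @return one-row data.frame with \code{gamma_amplitude},
#'   \code{gamma_frequency}, \code{gamma_phase}, \code{theta_amplitude},
#'   \code{theta_frequency}, \code{theta_asymmetry}, \code{cycle_id}.
#' @export
characterize_element <- function(patch, cycle, freqs = seq(15, 200, 5),
                                 n_bins = 36) {
  cells <- patch$cells
  stopifnot(nrow(cells) > 0)
  w <- cells$amplitude
  bin_deg <- 360 / n_bins
  phase_centers <- (cells$col - 0.5) * bin_deg
  data.frame(
    gamma_amplitude = mean(cells$amplitude),
    gamma_frequency = sum(w * freqs[cells$row]) / sum(w),
    gamma_phase = circular_mean_deg(phase_centers, w),
    theta_amplitude = cycle$amplitude,
    theta_frequency = cycle$frequency,
    theta_asymmetry = cycle$asymmetry,
    cycle_id = cycle$cycle_id)
}

#' Slow/medium gamma band ratio of a frequency distribution
#'
#' Locates the density modes inside the slow (25-50 Hz) and medium
#' (60-100 Hz) gamma bands and sums the probability over the contiguous
#' bins around each mode whose density is at least half the mode density.
#' Returns \code{(mass_M - mass_S) / (mass_M + mass_S)}, in [-1, 1]; a
#' band with no density contributes zero mass, and an error is raised when
#' both masses vanish.
#'
#' @param density probability masses over the frequency grid (normalized).
#' @param freqs frequency grid in Hz.
#' @param slow,medium band limits in Hz.
#' @return list with \code{ratio}, \code{mass_S}, \code{mass_M}.
#' @export
gamma_band_ratio <- function(density, freqs, slow = c(25, 50),
                             medium = c(60, 100)) {
  stopifnot(length(density) == length(freqs))
  mode_mass <- function(band) {
    inb <- which(freqs >= band[1] & freqs <= band[2])
    if (!length(inb) || all(density[inb] <= 0)) return(0)
    mode_i <- inb[which.max(density[inb])]
    half <- density[mode_i] / 2
    lo <- mode_i
    while (lo > 1 && density[lo - 1] >= half) lo <- lo - 1
    hi <- mode_i
    while (hi < length(density) && density[hi + 1] >= half) hi <- hi + 1
    sum(density[lo:hi])
  }
  mS <- mode_mass(slow)
  mM <- mode_mass(medium)
  if (mS + mM == 0) stop("gamma_band_ratio: no density in either band")
  list(ratio = (mM - mS) / (mM + mS), mass_S = mS, mass_M = mM)
}

#' Bootstrap Kullback-Leibler comparison of two feature samples
#'
#' Repeatedly subsamples both groups, histograms them on a common grid
#' (with additive smoothing of empty bins) and measures the
#' Kullback-Leibler divergence of A from B. The null distribution is built
#' by the same procedure after shuffling the group labels; the observed
#' mean divergence is called significant when it exceeds the upper 95%
#' bound of the null.
#'
#' @param a,b numeric samples of a scalar feature.
#' @param reps bootstrap repetitions (default 2000).
#' @param subsample subsample size per repetition (default 1500).
#' @param n_bins histogram bins (default 30).
#' @return list with \code{divergence} (mean observed KL), \code{null_q95},
#'   \code{significant}.
#' @export
compare_distributions_kl <- function(a, b, reps = 2000, subsample = 1500,
                                     n_bins = 30) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  breaks <- seq(min(a, b), max(a, b), length.out = n_bins + 1)
  pdf_of <- function(x) {
    h <- tabulate(pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1),
                       n_bins), n_bins)
    p <- h + 0.5                      # additive smoothing of empty bins
    p / sum(p)
  }
  kl <- function(p, q) sum(p * log2(p / q))
  one_rep <- function(x, y) {
    kl(pdf_of(sample(x, subsample, replace = TRUE)),
       pdf_of(sample(y, subsample, replace = TRUE)))
  }
  obs <- replicate(reps, one_rep(a, b))
  pool <- c(a, b)
  na <- length(a)
  null <- replicate(reps, {
    idx <- sample.int(length(pool), na)
    one_rep(pool[idx], pool[-idx])
  })
  q95 <- quantile(null, 0.95, names = FALSE)
  list(divergence = mean(obs), null_q95 = q95,
       significant = mean(obs) > q95)
}
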