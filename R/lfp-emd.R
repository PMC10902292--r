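#' Ensemble empirical mode decomposition of an LFP trace
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by ensemble
#' empirical mode decomposition: white Gaussian noise scaled to
#' \code{noise_level} times the signal standard deviation is added in each
#' realization, the noisy signal is sifted into IMFs, and the ensemble mean
#' is taken per IMF index. The mean Hilbert-derived instantaneous frequency
#' of each IMF is attached so that band composites can be formed by summing
#' in-band modes. The residual is defined as the input minus the summed
#' IMFs, so reconstruction is exact by construction.
#'
#' @param x numeric signal (finite, at least one second of samples).
#' @param fs sampling rate in Hz (default 1000).
#' @param n_imfs number of IMFs to request (default 10).
#' @param n_realizations ensemble size (default 2000; analyses at reduced
#'   scale may lower this, see the methods vignette).
#' @param noise_level noise standard deviation as a fraction of the signal
#'   standard deviation (default 0.3).
#' @param freq_stat how to summarize instantaneous frequency per IMF,
#'   \code{"mean"} (default) or \code{"median"}.
#' @param sd_tol,max_sift sifting stop criterion (Cauchy-type tolerance)
#'   and maximum sift iterations per IMF.
#' @return an object of class \code{imf_set}: list with \code{imfs}
#'   (samples x n_imfs matrix), \code{residual}, \code{mean_freq} (Hz per
#'   IMF, NA for all-zero modes), \code{fs}.
#' @export
decompose_signal <- function(x, fs = 1000, n_imfs = 10, n_realizations = 2000,
                             noise_level = 0.3, freq_stat = c("mean", "median"),
                             sd_tol = 0.2, max_sift = 12) {
  freq_stat <- match.arg(freq_stat)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("decompose_signal: input must be finite numeric")
  if (length(x) < fs)
    stop("decompose_signal: need at least 1 s of signal")
  noise_sd <- noise_level * sd(x)
  imfs <- if (n_realizations <= 1 || noise_sd == 0) {
    .emd_cpp(x, n_imfs, sd_tol, max_sift)
  } else {
    .eemd_cpp(x, n_imfs, n_realizations, noise_sd, sd_tol, max_sift)
  }
  mean_freq <- apply(imfs, 2, function(m) {
    if (all(m == 0)) return(NA_real_)
    f <- instantaneous_frequency(m, fs)
    # drop edge samples, which carry unwrap artifacts
    k <- max(1, round(0.01 * length(f)))
    f <- f[(k + 1):(length(f) - k)]
    if (freq_stat == "mean") mean(f) else median(f)
  })
  structure(list(imfs = imfs, residual = x - rowSums(imfs),
                 mean_freq = mean_freq, fs = fs),
            class = "imf_set")
}

#' Band composite from an IMF set
#'
#' Sums the IMFs whose mean instantaneous frequency falls inside the
#' requested band. Recognized bands: \code{"theta"} (4-12 Hz),
#' \code{"gamma"} (30-250 Hz), \code{"infra"} (1-4 Hz). A numeric
#' \code{c(lo, hi)} is also accepted. Returns a zero signal when no IMF
#' lies in the band.
#'
#' @param imfset an \code{imf_set} from [decompose_signal()].
#' @param band band label or numeric bounds in Hz.
#' @return numeric composite signal.
#' @export
band_composite <- function(imfset, band) {
  stopifnot(inherits(imfset, "imf_set"))
  if (is.character(band)) {
    band <- switch(band,
      theta = c(4, 12), gamma = c(30, 250), infra = c(1, 4),
      stop("band_composite: unknown band '", band, "'"))
  }
  stopifnot(is.numeric(band), length(band) == 2)
  sel <- which(!is.na(imfset$mean_freq) &
                 imfset$mean_freq >= band[1] & imfset$mean_freq <= band[2])
  if (length(sel) == 0) return(numeric(nrow(imfset$imfs)))
  rowSums(imfset$imfs[, sel, drop = FALSE])
}
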