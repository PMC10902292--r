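#' Complex Morlet wavelet amplitude spectrogram
#'
#' Convolves a signal with complex Morlet wavelets of 0.5 s duration on a
#' frequency grid (default 15 to 200 Hz in 5 Hz steps, 38 rows) whose cycle
#' counts depend linearly on frequency (6 cycles at the lowest frequency to
#' 20 at the highest). Convolution is done in the frequency domain; kernels
#' are L2-normalized so a unit-amplitude tone yields a flat envelope at its
#' own row away from the edges.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies in Hz (default \code{seq(15, 200, 5)}).
#' @param cycles numeric length-2, cycle count at the first and last
#'   frequency (default \code{c(6, 20)}).
#' @param duration kernel duration in seconds (default 0.5).
#' @return a \code{spectrogram}: list with \code{amplitude} (freq x time
#'   matrix), \code{freqs}, \code{fs}.
#' @export
wavelet_amplitude <- function(x, fs = 1000, freqs = seq(15, 200, by = 5),
                              cycles = c(6, 20), duration = 0.5) {
  stopifnot(is.numeric(x))
  n <- length(x)
  klen <- round(duration * fs)
  if (klen %% 2 == 0) klen <- klen + 1
  if (n <= klen) stop("wavelet_amplitude: signal shorter than the kernel")
  ncyc <- cycles[1] + (freqs - freqs[1]) / (max(freqs) - freqs[1]) *
    (cycles[2] - cycles[1])
  nfft <- nextn(n + klen - 1, 2)
  X <- fft(c(x, numeric(nfft - n)))
  half <- (klen - 1) / 2
  tk <- (seq_len(klen) - 1 - half) / fs
  amp <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma <- ncyc[i] / (2 * pi * f)
    gauss <- exp(-tk^2 / (2 * sigma^2))
    # scaled so a unit-amplitude tone at f gives an envelope of 1
    kern <- gauss * exp(2i * pi * f * tk) * (2 / sum(gauss))
    K <- fft(c(kern, complex(real = numeric(nfft - klen))))
    conv <- fft(X * K, inverse = TRUE) / nfft
    amp[i, ] <- Mod(conv[(half + 1):(half + n)])
  }
  structure(list(amplitude = amp, freqs = freqs, fs = fs),
            class = "spectrogram")
}

#' Current source density across a laminar probe
#'
#' Discrete second spatial derivative of the channel profile:
#' \code{CSD(n, t) = (-x[n-1, t] + 2 x[n, t] - x[n+1, t]) / dd^2}, defined
#' for interior channels only. A potential linear in depth maps to zero.
#'
#' @param samples time x channel numeric matrix.
#' @param spacing_mm inter-channel spacing in mm (default 0.05, i.e. 50 um).
#' @return time x (channels - 2) matrix; column \code{k} is the CSD at
#'   input channel \code{k + 1}. Attribute \code{channels} stores the
#'   original channel indices.
#' @export
compute_csd <- function(samples, spacing_mm = 0.05) {
  samples <- as.matrix(samples)
  nc <- ncol(samples)
  if (nc < 3) stop("compute_csd: need at least 3 channels")
  interior <- 2:(nc - 1)
  csd <- (-samples[, interior - 1] + 2 * samples[, interior] -
            samples[, interior + 1]) / spacing_mm^2
  csd <- matrix(csd, nrow = nrow(samples))
  attr(csd, "channels") <- interior
  csd
}

#' Locate the hippocampal fissure from the theta-power depth profile
#'
#' Theta power per channel is measured with a low-frequency Morlet bank
#' (1-14 Hz, 2 s kernels, 2-4 cycles) applied to the theta-filtered trace,
#' and a Gaussian is fitted to the power-versus-depth curve. The fissure is
#' the fitted peak location, possibly between two electrodes. Degenerate
#' (monotone or flat) profiles fall back to the argmax with a warning.
#'
#' @param samples time x channel matrix at rate \code{fs}.
#' @param fs sampling rate in Hz.
#' @return list with \code{position} (fractional channel index),
#'   \code{channel} (nearest integer channel), \code{power} (per-channel
#'   theta power profile).
#' @export
locate_fissure <- function(samples, fs = 1000) {
  samples <- as.matrix(samples)
  nc <- ncol(samples)
  if (nc < 4) stop("locate_fissure: need at least 4 channels")
  power <- vapply(seq_len(nc), function(ch) {
    x <- theta_bandpass(samples[, ch], fs)
    sp <- wavelet_amplitude(x, fs, freqs = seq(1, 14, by = 1),
                            cycles = c(2, 4), duration = 2)
    sel <- sp$freqs >= 4 & sp$freqs <= 12
    mean(sp$amplitude[sel, ]^2)
  }, numeric(1))
  fit_gaussian_peak(power)
}

# zero-phase FIR theta bandpass (4-12 Hz), order 256
theta_bandpass <- function(x, fs, band = c(4, 12), order = 256) {
  h <- signal::fir1(order, band / (fs / 2), type = "pass")
  signal::filtfilt(as.numeric(h), 1, x)
}

# Gaussian fit of a unimodal profile; returns fractional peak position.
fit_gaussian_peak <- function(power) {
  nc <- length(power)
  ch <- seq_len(nc)
  amax <- which.max(power)
  degenerate <- amax == 1 || amax == nc || sd(power) == 0
  pos <- as.numeric(amax)
  if (!degenerate) {
    fit <- tryCatch(
      suppressWarnings(
        nls(power ~ a * exp(-(ch - mu)^2 / (2 * s2)) + b,
            start = list(a = max(power) - min(power), mu = amax,
                         s2 = (nc / 4)^2, b = min(power)),
            control = list(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      mu <- coef(fit)[["mu"]]
      if (mu >= 1 && mu <= nc) pos <- mu else degenerate <- TRUE
    } else degenerate <- TRUE
  }
  if (degenerate)
    warning("locate_fissure: degenerate theta-power profile, using argmax")
  list(position = pos, channel = as.integer(round(pos)), power = power)
}
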