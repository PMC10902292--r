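#' @useDynLib gammel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile median approx coef nls fft
#'   nextn predict complete.cases aggregate
#' @importFrom utils head tail read.csv write.csv
NULL

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal whose real part is the input and
#' whose modulus is the instantaneous amplitude envelope.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous frequency of a signal
#'
#' Derivative of the unwrapped analytic-signal phase, converted to Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return numeric vector of length \code{length(x) - 1}.
#' @export
instantaneous_frequency <- function(x, fs) {
  ph <- unwrap_phase(Arg(analytic_signal(x)))
  diff(ph) * fs / (2 * pi)
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Circular mean of angles in degrees
#'
#' @param deg angles in degrees.
#' @param w optional nonnegative weights.
#' @return mean direction in [0, 360).
#' @export
circular_mean_deg <- function(deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(deg))
  rad <- deg * pi / 180
  ang <- Arg(sum(w * exp(1i * rad)))
  out <- (ang * 180 / pi) %% 360
  if (out > 360 - 1e-9) out <- 0
  out
}

# Morlet-style burst waveform: Gaussian-windowed cosine with a given number
# of cycles (full width of the Gaussian at 1 sd spans n_cycles/freq seconds).
morlet_burst <- function(t, center, freq, amplitude, n_cycles = 6, phase0 = 0) {
  sigma <- n_cycles / (2 * pi * freq)
  amplitude * exp(-((t - center)^2) / (2 * sigma^2)) *
    cos(2 * pi * freq * (t - center) + phase0)
}

# derive a child seed from a base seed and a small offset, kept < 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}
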