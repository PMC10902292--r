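#' Parameters of the theta-driven QIF excitatory-inhibitory network
#'
#' Quadratic integrate-and-fire network of \code{n} neurons (fraction
#' \code{frac_E} excitatory) with quenched Gaussian in-degrees within each
#' population, all-to-all cross-population coupling, Gaussian-distributed
#' excitabilities and a sinusoidal theta-frequency drive. DC currents scale
#' as \code{I0 * sqrt(K)} and couplings as \code{g0 / sqrt(K)}, yielding
#' balanced dynamics at large K.
#'
#' @param n total neurons (default 2000).
#' @param frac_E excitatory fraction (default 0.8).
#' @param tau_E,tau_I membrane time constants in ms (10, 4.5).
#' @param I0_E,I0_I mean excitabilities (0.3, 0.25).
#' @param D_E,D_I excitability standard deviations (0.1*I0_E, I0_I).
#' @param K median in-degree scale (default 20).
#' @param Delta_EE,Delta_II in-degree standard deviations (2K, 0.2K; the
#'   final-value reading of the heterogeneity parameters).
#' @param g0_EE,g0_II,g0_EI,g0_IE unscaled synaptic couplings. The printed
#'   parameter chain is ambiguous for the I-to-I coupling;
#'   \code{gii_reading = "large"} (default) uses \code{g0_II = 1.44} with
#'   \code{g0_EI = g0_IE = 0.01}, \code{"small"} uses
#'   \code{g0_II = 0.0144}.
#' @param A,nu theta drive amplitude (0.042, scaled by sqrt(K)) and
#'   frequency in Hz (10).
#' @param vb spike/reset boundary of the QIF phase variable (default 100).
#' @param dt Euler step in ms (default 0.001).
#' @param gii_reading see \code{g0_II}.
#' @param seed integer seed for connectivity and excitability draws.
#' @return list of class \code{network_params}.
#' @export
network_params <- function(n = 2000, frac_E = 0.8, tau_E = 10, tau_I = 4.5,
                           I0_E = 0.3, I0_I = 0.25,
                           D_E = 0.1 * I0_E, D_I = I0_I,
                           K = 20, Delta_EE = 2 * K, Delta_II = 0.2 * K,
                           g0_EE = 0.27, g0_II = NULL, g0_EI = 0.01,
                           g0_IE = 0.01, A = 0.042, nu = 10, vb = 100,
                           dt = 0.001, gii_reading = c("large", "small"),
                           seed = 0) {
  gii_reading <- match.arg(gii_reading)
  if (is.null(g0_II))
    g0_II <- if (gii_reading == "large") 1.44 else 0.0144
  stopifnot(tau_E > 0, tau_I > 0, frac_E > 0, frac_E < 1, K >= 1)
  structure(list(n = n, frac_E = frac_E, tau_E = tau_E, tau_I = tau_I,
                 I0_E = I0_E, I0_I = I0_I, D_E = D_E, D_I = D_I, K = K,
                 Delta_EE = Delta_EE, Delta_II = Delta_II,
                 g0_EE = g0_EE, g0_II = g0_II, g0_EI = g0_EI,
                 g0_IE = g0_IE, A = A, nu = nu, vb = vb, dt = dt,
                 tau_rA = 0.4, tau_dA = 2, tau_rG = 0.25, tau_dG = 5,
                 seed = seed),
            class = "network_params")
}

# quenched within-population adjacency: per postsynaptic neuron draw a
# Gaussian in-degree (truncated to [1, pop size]) and sample that many
# presynaptic partners; returned as out-edge lists (presyn -> posts).
build_adjacency <- function(n_pop, K, Delta) {
  out <- vector("list", n_pop)
  for (l in seq_len(n_pop)) out[[l]] <- integer(0)
  indeg <- pmin(pmax(round(rnorm(n_pop, K, Delta)), 1L), n_pop - 1L)
  for (j in seq_len(n_pop)) {
    pres <- sample(setdiff(seq_len(n_pop), j), indeg[j])
    for (l in pres) out[[l]] <- c(out[[l]], j)
  }
  out
}

#' Simulate the QIF network
#'
#' Euler integration of the network equations with delta-pulse synapses;
#' the model LFP (sum over excitatory neurons of the absolute AMPA and
#' GABA currents, 1 Hz high-passed with a 4th-order Butterworth filter),
#' the mean inhibitory membrane potential and the spike raster are
#' recorded at 1 kHz. Deterministic given the seed.
#'
#' @param params a [network_params()].
#' @param duration_s simulated span in seconds.
#' @param transient_s initial span discarded from the recorded traces
#'   (default 0.5 s); spikes are reported from t = 0.
#' @return list of class \code{network_sim}: \code{raster} (data.frame
#'   \code{neuron}, \code{time_ms}, \code{pop}), \code{lfp} (filtered),
#'   \code{lfp_raw}, \code{vI_mean}, \code{theta_phase} (radians per
#'   sample), \code{fs} (1000), \code{rates} (Hz per neuron),
#'   \code{params}.
#' @export
simulate_network <- function(params, duration_s, transient_s = 0.5) {
  stopifnot(inherits(params, "network_params"))
  set.seed(child_seed(params$seed, 31))
  nE <- round(params$n * params$frac_E)
  nI <- params$n - nE
  sK <- sqrt(params$K)
  Ie <- rnorm(nE, params$I0_E, params$D_E) * sK
  Ii <- rnorm(nI, params$I0_I, params$D_I) * sK
  adjEE <- build_adjacency(nE, params$K, params$Delta_EE)
  adjII <- build_adjacency(nI, params$K, params$Delta_II)
  res <- .qif_sim_cpp(nE, nI, params$tau_E, params$tau_I, Ie, Ii,
                      params$g0_EE / sK, params$g0_EI / sK,
                      params$g0_IE / sK, params$g0_II / sK,
                      adjEE, adjII, params$A * sK, params$nu,
                      params$vb, params$dt, duration_s * 1000, 1,
                      params$tau_rA, params$tau_dA,
                      params$tau_rG, params$tau_dG,
                      transient_s * 1000)
  raster <- data.frame(neuron = res$spike_neuron, time_ms = res$spike_time,
                       pop = ifelse(res$spike_neuron <= nE, "E", "I"))
  lfp <- highpass_1hz(res$lfp, fs = 1000)
  rates <- tabulate(res$spike_neuron, nbins = params$n) / duration_s
  structure(list(raster = raster, lfp = lfp, lfp_raw = res$lfp,
                 vI_mean = res$vI_mean, theta_phase = res$theta_phase,
                 fs = 1000, rates = rates, nE = nE, nI = nI,
                 params = params, duration_s = duration_s,
                 transient_s = transient_s,
                 out_degree_EE = lengths(adjEE)),
            class = "network_sim")
}

highpass_1hz <- function(x, fs) {
  bf <- signal::butter(4, 1 / (fs / 2), type = "high")
  signal::filtfilt(bf, x)
}

#' Closed-form synaptic impulse response
#'
#' Solution of the double-exponential current equations for a single
#' presynaptic spike at t = 0:
#' \code{I(t) = gain / (tau_d - tau_r) * (exp(-t/tau_d) - exp(-t/tau_r))},
#' where \code{gain} is the charge injected into the rise variable
#' (\code{2 * tau_m * g} per delivered spike).
#'
#' @param t time since the spike in ms (vector; negative times give 0).
#' @param tau_r,tau_d rise and decay constants in ms.
#' @param gain injected charge.
#' @return current at \code{t}.
#' @export
synaptic_impulse_response <- function(t, tau_r, tau_d, gain = 1) {
  ifelse(t < 0, 0,
         gain / (tau_d - tau_r) * (exp(-t / tau_d) - exp(-t / tau_r)))
}

#' Model LFP from a spike raster
#'
#' Event-based reconstruction of the simulated LFP: every excitatory spike
#' contributes its out-degree times the AMPA impulse response, every
#' inhibitory spike contributes (all-to-all) \code{nE} times the GABA
#' impulse response; both kernels are the closed-form double exponentials.
#' Since all contributions are nonnegative the sum of absolute currents
#' equals the plain sum. The result is 1 Hz high-passed.
#'
#' @param raster data.frame with \code{neuron} and \code{time_ms} (E
#'   neurons are \code{1..nE}).
#' @param params a [network_params()].
#' @param nE,nI population sizes (defaults derived from \code{params}).
#' @param out_degree_EE out-degree per E neuron (default: the expected
#'   value K for all).
#' @param duration_s trace length in seconds.
#' @return list with \code{lfp} (filtered), \code{lfp_raw}, \code{fs}.
#' @export
synthesize_model_lfp <- function(raster, params,
                                 nE = round(params$n * params$frac_E),
                                 nI = params$n - nE,
                                 out_degree_EE = NULL,
                                 duration_s = NULL) {
  if (is.null(duration_s))
    duration_s <- if (nrow(raster)) max(raster$time_ms) / 1000 + 0.1 else 1
  fs <- 1000
  tt <- seq_len(round(duration_s * fs)) / fs * 1000   # ms
  sK <- sqrt(params$K)
  gainA <- 2 * params$tau_E * params$g0_EE / sK
  gainG <- 2 * params$tau_E * params$g0_EI / sK
  if (is.null(out_degree_EE)) out_degree_EE <- rep(params$K, nE)
  lfp <- numeric(length(tt))
  for (i in seq_len(nrow(raster))) {
    ts <- raster$time_ms[i]
    idx <- which(tt >= ts & tt <= ts + 60)
    if (!length(idx)) next
    if (raster$neuron[i] <= nE) {
      lfp[idx] <- lfp[idx] + out_degree_EE[raster$neuron[i]] *
        synaptic_impulse_response(tt[idx] - ts, params$tau_rA,
                                  params$tau_dA, gainA)
    } else {
      lfp[idx] <- lfp[idx] + nE *
        synaptic_impulse_response(tt[idx] - ts, params$tau_rG,
                                  params$tau_dG, gainG)
    }
  }
  list(lfp = if (length(lfp) > 24) highpass_1hz(lfp, fs) else lfp,
       lfp_raw = lfp, fs = fs)
}

#' Spectral entropy of a signal over the gamma range
#'
#' Shannon entropy of the power spectral density normalized over a
#' 25-125 Hz grid at 0.1 Hz resolution (M = 1000 bins), divided by
#' log2(M) so that 1 means spectrally flat and 0 a single line.
#'
#' @param x signal (at least 10 s for the stated resolution).
#' @param fs sampling rate in Hz.
#' @param f_min,f_max,df band and resolution in Hz (25, 125, 0.1).
#' @return value in [0, 1].
#' @export
spectral_entropy <- function(x, fs, f_min = 25, f_max = 125, df = 0.1) {
  if (length(x) < 10 * fs)
    stop("spectral_entropy: need at least 10 s of signal")
  ps <- band_periodogram(x, fs, f_min, f_max, df)
  if (sum(ps) == 0) stop("spectral_entropy: no power in band")
  p <- ps / sum(ps)
  M <- round((f_max - f_min) / df)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz])) / log2(M)
}

# periodogram power binned onto a regular frequency grid
band_periodogram <- function(x, fs, f_min, f_max, df) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  half <- fr <= fs / 2
  fr <- fr[half]; P <- P[half]
  edges <- seq(f_min, f_max, by = df)
  bin <- findInterval(fr, edges, rightmost.closed = FALSE)
  sel <- bin >= 1 & bin <= length(edges) - 1 & fr >= f_min & fr < f_max
  out <- numeric(length(edges) - 1)
  agg <- tapply(P[sel], bin[sel], mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Low/high gamma power ratio
#'
#' \code{r_gamma = (P_low - P_high) / (P_high + P_low)} with the low band
#' 25-50 Hz and the high band 50-100 Hz, computed exactly as printed.
#'
#' @param x signal.
#' @param fs sampling rate in Hz.
#' @return value in [-1, 1].
#' @export
gamma_power_ratio <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  p_low <- sum(P[fr >= 25 & fr < 50])
  p_high <- sum(P[fr >= 50 & fr <= 100])
  if (p_low + p_high == 0) stop("gamma_power_ratio: zero band power")
  (p_low - p_high) / (p_high + p_low)
}

#' Binary entropy of per-gamma-cycle firing
#'
#' The probability that a gamma cycle contains a spike is estimated as
#' the firing rate divided by the gamma frequency and plugged into
#' \code{H = -p log2 p - (1-p) log2 (1-p)}.
#'
#' @param rate firing rate in Hz.
#' @param gamma_frequency mean gamma frequency in Hz.
#' @return entropy in bits.
#' @export
spike_train_entropy <- function(rate, gamma_frequency) {
  p <- rate / gamma_frequency
  if (any(p > 1)) {
    warning("spike_train_entropy: rate above gamma frequency, clipping p to 1")
    p <- pmin(p, 1)
  }
  p <- pmax(p, 0)
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

#' Phase concentration of spike theta phases
#'
#' Modulus of the mean unit phasor of the spike phases; 1 for perfect
#' phase locking, 0 for uniform phases.
#'
#' @param phases spike phases.
#' @param degrees interpret input in degrees (default) or radians.
#' @return value in [0, 1].
#' @export
phase_concentration <- function(phases, degrees = TRUE) {
  if (!length(phases)) stop("phase_concentration: no spikes")
  rad <- if (degrees) phases * pi / 180 else phases
  Mod(mean(exp(-1i * rad)))
}

#' Indicators of the network dynamic regime over a parameter grid
#'
#' Simulates the network at every combination of \code{K} and
#' \code{g0_IE} values and reports, per point: spectral entropy and
#' low/high gamma ratio of the model LFP, the standard deviation over
#' time of the mean inhibitory membrane potential, and the mean
#' excitatory spike-train entropy (gamma frequency taken at the LFP
#' spectral peak in 25-125 Hz).
#'
#' @param K_values,gIE_values grid values.
#' @param base a [network_params()] used for all other parameters.
#' @param duration_s simulated span per point.
#' @return data.frame with one row per grid point; failed points carry NA
#'   indicators.
#' @export
sweep_regimes <- function(K_values, gIE_values, base = network_params(),
                          duration_s = 20) {
  grid <- expand.grid(K = K_values, g0_IE = gIE_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    p$K <- grid$K[i]
    p$Delta_EE <- 2 * p$K
    p$Delta_II <- 0.2 * p$K
    p$g0_IE <- grid$g0_IE[i]
    out <- data.frame(K = p$K, g0_IE = p$g0_IE, spectral_entropy = NA_real_,
                      r_gamma = NA_real_, vI_sd = NA_real_,
                      spike_entropy = NA_real_, rate_E = NA_real_,
                      gamma_peak_hz = NA_real_)
    sim <- tryCatch(simulate_network(p, duration_s), error = function(e) NULL)
    if (is.null(sim)) return(out)
    out$spectral_entropy <- spectral_entropy(sim$lfp, sim$fs)
    out$r_gamma <- gamma_power_ratio(sim$lfp, sim$fs)
    out$vI_sd <- sd(sim$vI_mean)
    ps <- band_periodogram(sim$lfp, sim$fs, 25, 125, 0.1)
    out$gamma_peak_hz <- 25 + (which.max(ps) - 0.5) * 0.1
    ratesE <- sim$rates[seq_len(sim$nE)]
    out$rate_E <- mean(ratesE)
    out$spike_entropy <- mean(spike_train_entropy(
      pmin(ratesE, out$gamma_peak_hz), out$gamma_peak_hz))
    out
  })
  do.call(rbind, rows)
}

#' Extract gamma elements from a simulated model LFP
#'
#' The model has no laminar probe, so theta cycles are taken from the
#' known sinusoidal forcing (peaks of the 10 Hz drive delimit cycles) and
#' the Morlet/snippet/patch pipeline is applied to the LFP spectrogram
#' directly.
#'
#' @param sim a \code{network_sim}.
#' @param max_per_cycle maximum elements per cycle (default 4).
#' @return element data.frame (as [extract_gamma_elements()], without
#'   behavior columns) with \code{t_center} in seconds relative to the
#'   recorded trace.
#' @export
model_gamma_elements <- function(sim, max_per_cycle = 4) {
  fs <- sim$fs
  x <- sim$lfp
  nu <- sim$params$nu
  period <- round(fs / nu)
  spec <- wavelet_amplitude(x, fs)
  # forcing peaks: cos phase 0 at t=0 of the full simulation; the recorded
  # trace starts at the transient cutoff
  offset_ms <- sim$transient_s * 1000
  first_peak <- ceiling(offset_ms * nu / 1000) * 1000 / nu - offset_ms
  peaks <- round(seq(first_peak, length(x) - period, by = 1000 / nu))
  peaks <- peaks[peaks >= 1]
  cand <- data.frame(
    cycle_id = seq_len(length(peaks) - 1),
    start_peak = peaks[-length(peaks)],
    desc_flank = peaks[-length(peaks)] + round(period / 4),
    trough = peaks[-length(peaks)] + round(period / 2),
    asc_flank = peaks[-length(peaks)] + round(3 * period / 4),
    end_peak = peaks[-1])
  cand$duration_ms <- (cand$end_peak - cand$start_peak) / fs * 1000
  cand$amplitude <- sim$params$A * sqrt(sim$params$K) * 2
  cand$frequency <- nu
  cand$asymmetry <- 1
  snippets <- lapply(seq_len(nrow(cand)), function(k)
    build_cycle_snippet(spec, cand[k, ]))
  out <- list()
  for (k in seq_len(nrow(cand))) {
    nb <- list(prev = if (k > 1) snippets[[k - 1]],
               next_ = if (k < nrow(cand)) snippets[[k + 1]])
    patches <- detect_patches(snippets[[k]], neighbors = nb,
                              max_count = max_per_cycle)
    if (!length(patches)) next
    cyc <- cand[k, ]
    els <- do.call(rbind, lapply(patches, characterize_element,
                                 cycle = cyc, freqs = spec$freqs))
    els$t_center <- vapply(els$gamma_phase, function(p)
      approx(c(0, 90, 180, 270, 360),
             c(cyc$start_peak, cyc$desc_flank, cyc$trough, cyc$asc_flank,
               cyc$end_peak), xout = p %% 360)$y / fs, numeric(1))
    els$channel <- 1
    out[[length(out) + 1]] <- els
  }
  if (!length(out)) return(empty_element_table())
  do.call(rbind, out)
}

#' Decode single-neuron spiking from gamma elements
#'
#' For each selected excitatory neuron, a class-balanced boosted-tree
#' binary classifier predicts the presence of at least one spike in a
#' window centered on each gamma element, from the element's feature
#' vector. Cross-validation folds group elements by theta cycle. Reports
#' TP and TN fractions (per-class correct rates), precision, recall, the
#' decodable flag (TP > 0.6 and TN > 0.6) and the theta phase
#' concentration of each neuron's spikes.
#'
#' @param elements element table from [model_gamma_elements()].
#' @param sim the \code{network_sim} the elements came from.
#' @param neurons E neuron indices to decode; by default up to 50 E
#'   neurons whose spike-presence fraction across the element windows is
#'   nearest one half (neurons firing in almost every or almost no window
#'   carry a degenerate label and are skipped).
#' @param window_ms decoding window width (default 100).
#' @param config a [decoder_config()]; the default lowers the learner
#'   count to 100 for tractability at desk scale.
#' @return data.frame of class \code{spike_decoding_report}: one row per
#'   neuron with \code{neuron}, \code{rate}, \code{tp}, \code{tn},
#'   \code{fp}, \code{fn}, \code{precision}, \code{recall},
#'   \code{decodable}, \code{phase_concentration}.
#' @export
decode_spiking <- function(elements, sim, neurons = NULL, window_ms = 100,
                           config = decoder_config(max_learners = 100)) {
  stopifnot(nrow(elements) > 0)
  offset_ms <- sim$transient_s * 1000
  half <- window_ms / 2
  tc_ms <- elements$t_center * 1000
  presence <- function(nid) {
    st <- sim$raster$time_ms[sim$raster$neuron == nid] - offset_ms
    if (!length(st)) return(NA_real_)
    mean(vapply(tc_ms, function(tc) any(abs(st - tc) <= half), logical(1)))
  }
  if (is.null(neurons)) {
    cand <- which(sim$rates[seq_len(sim$nE)] > 0)
    frac <- vapply(cand, presence, numeric(1))
    ok <- !is.na(frac) & frac > 0.1 & frac < 0.9
    neurons <- head(cand[ok][order(abs(frac[ok] - 0.5))], 50)
  }
  rows <- list()
  for (nid in neurons) {
    st <- sim$raster$time_ms[sim$raster$neuron == nid] - offset_ms
    if (!length(st)) next
    lab <- vapply(elements$t_center * 1000, function(tc)
      any(abs(st - tc) <= half), logical(1))
    if (length(unique(lab)) < 2 || min(table(lab)) < config$n_folds) {
      rows[[length(rows) + 1]] <- data.frame(
        neuron = nid, rate = length(st) / sim$duration_s,
        tp = NA_real_, tn = NA_real_, fp = NA_real_, fn = NA_real_,
        precision = NA_real_, recall = NA_real_, decodable = NA,
        phase_concentration = spike_phase_conc(st, sim))
      next
    }
    tab <- elements
    tab$section <- ifelse(lab, "spike", "silent")
    rep <- evaluate_crossval(tab, config, n_boot = 1)
    pred <- rep$predictions
    ok <- !is.na(pred)
    tp <- mean(pred[ok & lab] == "spike")
    tn <- mean(pred[ok & !lab] == "silent")
    n_tp <- sum(pred[ok] == "spike" & lab[ok])
    n_fp <- sum(pred[ok] == "spike" & !lab[ok])
    n_fn <- sum(pred[ok] == "silent" & lab[ok])
    rows[[length(rows) + 1]] <- data.frame(
      neuron = nid, rate = length(st) / sim$duration_s,
      tp = tp, tn = tn, fp = 1 - tn, fn = 1 - tp,
      precision = if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else NA_real_,
      recall = if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else NA_real_,
      decodable = tp > 0.6 && tn > 0.6,
      phase_concentration = spike_phase_conc(st, sim))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("spike_decoding_report", "data.frame")
  out
}

spike_phase_conc <- function(spike_ms, sim) {
  ph <- 2 * pi * sim$params$nu * (spike_ms + sim$transient_s * 1000) / 1000
  phase_concentration(ph %% (2 * pi), degrees = FALSE)
}
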