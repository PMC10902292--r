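#' Quartile discretization of a feature
#'
#' Replaces values by their quartile label (Q1 lowest to Q4 highest),
#' which maximizes the single-variable entropy of the discretized
#' variable. Bin edges are the sample quartiles; values equal to an edge
#' go to the lower bin. Circular features are binned on their linearized
#' values by default (set \code{circular} for quartiles of the unwrapped
#' phase relative to the circular mean).
#'
#' @param values numeric vector (at least 8 finite values).
#' @param circular treat values as angles in degrees (default FALSE).
#' @return integer vector in 1..4 with attribute \code{edges}.
#' @export
discretize_quartiles <- function(values, circular = FALSE) {
  stopifnot(sum(is.finite(values)) >= 8)
  if (stats::var(values, na.rm = TRUE) == 0)
    stop("discretize_quartiles: constant input has zero entropy")
  v <- values
  if (circular) {
    mu <- circular_mean_deg(values)
    v <- ((values - mu + 180) %% 360) - 180
  }
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  lab <- 1L + (v > q[1]) + (v > q[2]) + (v > q[3])
  attr(lab, "edges") <- q
  lab
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between a feature pair and a target label
#'
#' Plug-in estimate from the joint frequency histogram of the discretized
#' inputs \code{f}, \code{g} and the categorical target \code{L}:
#' \code{I(f,g;L) = sum P(f,g,L) log2(P(f,g,L) / (P(f,g) P(L)))}, also
#' normalized by the target entropy \code{H(L)}.
#'
#' @param f,g discretized feature vectors (same length).
#' @param L categorical target (maze section labels).
#' @return list with \code{bits}, \code{normalized} (\code{bits / H(L)}),
#'   \code{H_L}.
#' @export
mutual_information_pair <- function(f, g, L) {
  if (length(f) != length(g) || length(f) != length(L))
    stop("mutual_information_pair: length mismatch")
  joint <- mi_bits(interaction(f, g, drop = TRUE), L)
  H_L <- entropy_bits(L)
  list(bits = joint, normalized = joint / H_L, H_L = H_L)
}

# plug-in mutual information between two categorical variables
mi_bits <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

#' Partial information decomposition under the minimal-mutual-information
#' ansatz
#'
#' Decomposes \code{I(f,g;L)} into unique, redundant and synergistic
#' parts with redundancy set to \code{min(I(f;L), I(g;L))}; the unique
#' information of the less informative input is then exactly zero and the
#' synergy follows from
#' \code{Syn = I(f,g;L) - I(f;L) - I(g;L) + Red}. Parts are nonnegative
#' and sum to the total.
#'
#' @param f,g discretized feature vectors.
#' @param L categorical target.
#' @return list of class \code{pid_result}: \code{total}, \code{unique_f},
#'   \code{unique_g}, \code{redundancy}, \code{synergy}, plus
#'   \code{normalized} (all parts divided by \code{H(L)}).
#' @export
pid_decompose <- function(f, g, L) {
  tot <- mutual_information_pair(f, g, L)
  parts <- pid_from_marginals(mi_bits(f, L), mi_bits(g, L), tot$bits)
  structure(c(as.list(parts),
              list(normalized = parts / tot$H_L, H_L = tot$H_L)),
            class = "pid_result")
}

#' PID algebra from marginal and joint mutual informations
#'
#' The arithmetic core of [pid_decompose()]: given \code{I(f;L)},
#' \code{I(g;L)} and \code{I(f,g;L)}, the minimal-mutual-information
#' redundancy is \code{min(I_f, I_g)}, the unique parts are the excesses
#' over it, and the synergy completes the total.
#'
#' @param I_f,I_g,I_joint mutual informations in bits.
#' @return named vector: \code{total}, \code{unique_f}, \code{unique_g},
#'   \code{redundancy}, \code{synergy}.
#' @export
pid_from_marginals <- function(I_f, I_g, I_joint) {
  red <- min(I_f, I_g)
  c(total = I_joint, unique_f = I_f - red, unique_g = I_g - red,
    redundancy = red, synergy = I_joint - I_f - I_g + red)
}

#' Normalized redundancy of a feature with speed
#'
#' \code{I(f;V) / H(f)}: the fraction of the feature's variation entropy
#' explained by speed. Both inputs should be quartile-discretized.
#'
#' @param f discretized feature.
#' @param speed discretized speed.
#' @return value in [0, 1].
#' @export
speed_redundancy <- function(f, speed) {
  H_f <- entropy_bits(f)
  if (H_f == 0) stop("speed_redundancy: zero feature entropy")
  mi_bits(f, speed) / H_f
}

#' Pairwise PID over all feature pairs of an element table
#'
#' Runs [pid_decompose()] for every pair of the six element features
#' (optionally plus speed) against the maze section.
#'
#' @param table element table.
#' @param include_speed add speed as a seventh input feature.
#' @return long-format data.frame: \code{feature_f}, \code{feature_g},
#'   \code{total}, \code{unique_f}, \code{unique_g}, \code{redundancy},
#'   \code{synergy}, \code{total_norm}, \code{synergy_frac}.
#' @export
pid_table <- function(table, include_speed = FALSE) {
  feats <- c("gamma_amplitude", "gamma_frequency", "gamma_phase",
             "theta_amplitude", "theta_frequency", "theta_asymmetry")
  if (include_speed) feats <- c(feats, "speed")
  disc <- lapply(feats, function(f) discretize_quartiles(table[[f]]))
  names(disc) <- feats
  L <- factor(table$section)
  rows <- list()
  for (i in seq_along(feats)) for (j in seq_along(feats)) {
    if (j <= i) next
    p <- pid_decompose(disc[[i]], disc[[j]], L)
    rows[[length(rows) + 1]] <- data.frame(
      feature_f = feats[i], feature_g = feats[j],
      total = p$total, unique_f = p$unique_f, unique_g = p$unique_g,
      redundancy = p$redundancy, synergy = p$synergy,
      total_norm = p$total / p$H_L,
      synergy_frac = if (p$total > 0) p$synergy / p$total else NA_real_)
  }
  do.call(rbind, rows)
}
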