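# shared fixture builders; everything is generated in code at test time

# add a Gaussian blob to a matrix
add_blob <- function(m, r0, c0, amp, sd = 1.5) {
  rr <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cc <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  m + amp * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sd^2))
}

# element table with section-dependent gamma frequency shift
toy_element_table <- function(n = 800, shift = 25, seed = 1,
                              sections = c("reward_RF", "target_arm",
                                           "other_RF", "other")) {
  set.seed(seed)
  section <- rep(sections, each = n / length(sections))
  mu <- 60 + shift * (as.integer(factor(section, levels = sections)) - 2.5)
  data.frame(
    gamma_amplitude = abs(rnorm(n, 1, 0.3)),
    gamma_frequency = rnorm(n, mu, 8),
    gamma_phase = runif(n, 0, 360),
    theta_amplitude = abs(rnorm(n, 2, 0.3)),
    theta_frequency = rnorm(n, 8, 0.5),
    theta_asymmetry = rnorm(n, 1.2, 0.1),
    section = section,
    speed = abs(rnorm(n, 25, 10)),
    cycle_id = rep(seq_len(n / 2), each = 2),
    channel = 1, trial = rep(1:4, each = n / 4))
}

# small synthetic recording with isolated burst channels; cached per session
.fixture_env <- new.env(parent = emptyenv())

small_recording <- function(duration_s = 12, seed = 11, noise_sd = 0.01,
                            modulation_map = list()) {
  key <- paste(duration_s, seed, noise_sd, length(modulation_map))
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  beh <- generate_behavior(seed = seed, n_trials = 2, n_days = 1)
  lay <- rep("extra", 16)
  lay[7] <- "rad"; lay[10] <- "l-m"; lay[12] <- "fissure"
  spec <- recording_spec(
    seed = seed, noise_sd = noise_sd, theta_asym = 1,
    layer_of_channel = lay, modulation_map = modulation_map,
    bursts = list(
      rad = burst_spec(rate = 1, freq_mean = 45, freq_sd = 5,
                       phase_mean = 315, phase_sd = 30, amp_mean = 3,
                       amp_sd = 0.5, fixed_count = TRUE),
      `l-m` = burst_spec(rate = 1, freq_mean = 85, freq_sd = 10,
                         phase_mean = 180, phase_sd = 30, amp_mean = 3,
                         amp_sd = 0.5, fixed_count = TRUE)))
  rec <- generate_recording(spec, beh, duration_s = duration_s)
  out <- list(behavior = beh, recording = rec)
  .fixture_env[[key]] <- out
  out
}

# independent oracle for the patch detector: full re-labeling connected
# component sweep at every distinct threshold using igraph, with explicit
# merge bookkeeping (pristine components freeze at their first merge)
oracle_patches <- function(mat, max_count = 4) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  nr <- nrow(mat); nc <- ncol(mat)
  cellid <- function(r, c) (c - 1) * nr + r
  grid_edges <- do.call(rbind, c(
    lapply(seq_len(nc), function(c) {
      r <- seq_len(nr - 1); cbind(cellid(r, c), cellid(r + 1, c))
    }),
    lapply(seq_len(nc - 1), function(c) {
      r <- seq_len(nr); cbind(cellid(r, c), cellid(r, c + 1))
    })))
  vals <- sort(unique(as.vector(mat[mat > 0])), decreasing = TRUE)
  comp_at <- function(thr) {
    act <- which(as.vector(mat) >= thr & as.vector(mat) > 0)
    keep <- grid_edges[grid_edges[, 1] %in% act & grid_edges[, 2] %in% act, ,
                       drop = FALSE]
    g <- if (nrow(keep)) {
      igraph::graph_from_edgelist(matrix(as.character(keep), ncol = 2),
                                  directed = FALSE)
    } else {
      igraph::make_empty_graph(directed = FALSE)
    }
    g <- g + igraph::vertices(setdiff(as.character(act),
                                      igraph::V(g)$name))
    mem <- igraph::components(g)$membership
    split(as.integer(names(mem)), mem)
  }
  frozen <- list()
  prev <- list()       # components at previous threshold (pristine only)
  tainted_sets <- list()
  is_sub <- function(a, b) all(a %in% b)
  for (thr in vals) {
    comps <- comp_at(thr)
    # map previous pristine components into current ones
    for (cur in comps) {
      inside <- Filter(function(p) is_sub(p, cur), prev)
      was_tainted <- any(vapply(tainted_sets, function(tset)
        is_sub(tset, cur), logical(1)))
      if (length(inside) >= 2 ||
          (length(inside) >= 1 && was_tainted)) {
        for (p in inside) frozen[[length(frozen) + 1]] <- p
        tainted_sets[[length(tainted_sets) + 1]] <- cur
      }
    }
    # pristine current components: those not containing a merge
    pristine <- Filter(function(cur) {
      inside <- Filter(function(p) is_sub(p, cur), prev)
      was_tainted <- any(vapply(tainted_sets, function(tset)
        is_sub(tset, cur), logical(1)))
      !(length(inside) >= 2 || was_tainted)
    }, comps)
    n_patches <- length(frozen) + length(pristine)
    if (n_patches >= max_count) {
      all_p <- c(frozen, pristine)
      return(rank_cells(all_p, mat, max_count))
    }
    prev <- pristine
  }
  rank_cells(c(frozen, prev), mat, max_count)
}

rank_cells <- function(patches, mat, max_count) {
  if (!length(patches)) return(list())
  nr <- nrow(mat)
  key <- t(vapply(patches, function(cells)
    c(mean(mat[cells]), mean((cells - 1) %/% nr + 1),
      mean((cells - 1) %% nr + 1)), numeric(3)))
  ord <- order(-key[, 1], key[, 2], key[, 3])
  unname(lapply(patches[ord][seq_len(min(max_count, length(patches)))],
                function(x) sort(as.integer(x))))
}

# canonical cell set of a detect_patches() result for comparison
patch_cells <- function(p, nr) {
  sort(as.integer(p$cells$row + (p$cells$col - 1) * nr))
}
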