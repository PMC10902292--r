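#' Detect gamma patches in a cycle snippet by threshold scanning
#'
#' Starting from the maximum amplitude, the detection threshold is lowered
#' through every distinct amplitude value of the snippet. Supra-threshold
#' cells form connected components under 4-neighborhood adjacency (no phase
#' wrap inside a cycle; continuity across cycles is handled through the
#' neighbor snippets). Components that merge as the threshold drops retain
#' their pre-merge extents and are stored as separate patches; the scan
#' stops at the first threshold at which \code{max_count} patches assigned
#' to this cycle have been identified, and the \code{max_count} strongest
#' (by mean amplitude, ties by earlier phase then lower frequency) are
#' returned.
#'
#' Components touching the first or last phase bin are resolved against the
#' adjacent cycles' snippets: the full cross-boundary extent is identified
#' on the concatenated phase axis and the patch is assigned to the cycle
#' holding the largest share of its summed amplitude (ties to the earlier
#' cycle), so no patch is counted twice.
#'
#' @param snippet frequency x phase-bin amplitude matrix (38 x 36 in the
#'   standard pipeline; any size is accepted). An optional \code{freqs}
#'   attribute gives the row frequencies in Hz.
#' @param neighbors optional list with elements \code{prev} and/or
#'   \code{next_} holding the adjacent cycles' snippets.
#' @param max_count maximum number of patches per cycle (default 4).
#' @param min_row_freq rows below this frequency (Hz) are excluded from
#'   patch formation when row frequencies are known (default 30; set to
#'   \code{NULL} to use all rows).
#' @return list of patches; each has \code{cells} (data.frame \code{row},
#'   \code{col}, \code{amplitude}; \code{col} is relative to this cycle's
#'   snippet and may exceed its bounds for cross-boundary patches),
#'   \code{mean_amplitude}, and \code{birth_threshold} (the amplitude at
#'   which the patch was last counted as separate).
#' @export
detect_patches <- function(snippet, neighbors = NULL, max_count = 4,
                           min_row_freq = 30) {
  snippet <- as.matrix(snippet)
  freqs <- attr(snippet, "freqs")
  nbin <- ncol(snippet)
  prev <- neighbors$prev
  nxt <- neighbors$next_
  blocks <- list(prev, snippet, nxt)
  have <- !vapply(blocks, is.null, logical(1))
  mat <- do.call(cbind, blocks[have])
  offset <- if (have[1]) nbin else 0L
  block_of <- rep(c(0L, 1L, 2L)[have],
                  times = vapply(blocks[have], ncol, integer(1)))

  row_ok <- rep(TRUE, nrow(mat))
  if (!is.null(freqs) && !is.null(min_row_freq))
    row_ok <- freqs >= min_row_freq

  res <- threshold_scan(mat, row_ok, max_count = max_count,
                        block_of = block_of, central = 1L)
  lapply(res, function(p) {
    cells <- data.frame(row = p$rows, col = p$cols - offset,
                        amplitude = mat[cbind(p$rows, p$cols)])
    list(cells = cells, mean_amplitude = mean(cells$amplitude),
         birth_threshold = p$birth_threshold)
  })
}

# Threshold sweep driver: the union-find scan itself runs in C++
# (src/patches.cpp); this wrapper shapes its output and applies the
# strongest-four ranking.
threshold_scan <- function(mat, row_ok, max_count, block_of, central) {
  amp <- as.vector(mat)
  res <- .threshold_scan_cpp(mat, row_ok, max_count,
                             as.integer(block_of), as.integer(central))
  if (!length(res)) return(list())
  central_p <- Filter(function(p) p$block == central, res)
  rank_patches(central_p, amp, nrow(mat), max_count)
}

rank_patches <- function(patches, amp, nr, max_count) {
  if (!length(patches)) return(list())
  key <- t(vapply(patches, function(p) {
    rows <- (p$cells - 1) %% nr + 1
    cols <- (p$cells - 1) %/% nr + 1
    c(mean(amp[p$cells]), mean(cols), mean(rows))
  }, numeric(3)))
  ord <- order(-key[, 1], key[, 2], key[, 3])
  out <- lapply(patches[ord], function(p) {
    list(rows = (p$cells - 1) %% nr + 1,
         cols = (p$cells - 1) %/% nr + 1,
         birth_threshold = p$birth_threshold)
  })
  out[seq_len(min(max_count, length(out)))]
}
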