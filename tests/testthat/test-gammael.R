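test_that("six disjoint blobs yield exactly the four strongest patches", {
  m <- matrix(0, 20, 30)
  pos <- cbind(c(4, 4, 10, 10, 16, 16), c(5, 15, 25, 5, 15, 25))
  amps <- c(5, 4, 3.5, 3, 2.5, 2)
  for (k in 1:6) m <- add_blob(m, pos[k, 1], pos[k, 2], amps[k], 1.2)
  p <- detect_patches(m, max_count = 4, min_row_freq = NULL)
  expect_length(p, 4)
  # the four returned patches sit on the four strongest blobs
  tops <- sapply(p, function(pp) {
    i <- which.max(pp$cells$amplitude)
    c(pp$cells$row[i], pp$cells$col[i])
  })
  expect_setequal(paste(tops[1, ], tops[2, ]),
                  paste(pos[1:4, 1], pos[1:4, 2]))
})

test_that("a single blob gives one patch; a sub-saddle join stays two", {
  m <- add_blob(matrix(0, 20, 20), 10, 10, 5)
  expect_length(detect_patches(m, min_row_freq = NULL), 1)
  m2 <- add_blob(add_blob(matrix(0, 10, 20), 5, 6, 5, 1.5), 5, 14, 4, 1.5)
  p2 <- detect_patches(m2, min_row_freq = NULL)
  expect_length(p2, 2)
  # each patch is on its own side of the saddle
  expect_setequal(sapply(p2, function(pp)
    pp$cells$col[which.max(pp$cells$amplitude)]), c(6, 14))
  expect_length(detect_patches(matrix(0, 10, 10), min_row_freq = NULL), 0)
})

test_that("patch detection matches the exhaustive threshold-sweep oracle", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (i in 1:60) {
    m <- matrix(round(runif(100), 2), 10, 10)
    if (i %% 3 == 0)
      m <- add_blob(add_blob(matrix(0, 10, 10), 3, 3, 2, 1.2),
                    7, 8, 1.5, 1.2) + matrix(round(runif(100), 2), 10) * 0.3
    mine <- lapply(detect_patches(m, min_row_freq = NULL),
                   patch_cells, nr = 10)
    orc <- oracle_patches(m)
    expect_identical(mine, orc)
  }
})

test_that("element characterization uses power-weighted (circular) means", {
  cyc <- data.frame(cycle_id = 7, amplitude = 2, frequency = 8,
                    asymmetry = 1.2)
  one <- list(cells = data.frame(row = 14, col = 18, amplitude = 5))
  e1 <- characterize_element(one, cyc)
  expect_equal(e1$gamma_amplitude, 5)
  expect_equal(e1$gamma_frequency, 80)       # row 14 of 15:5:200
  expect_equal(e1$gamma_phase, 175)          # bin 18 center
  expect_equal(e1$theta_amplitude, 2)
  two <- list(cells = data.frame(row = c(12, 16), col = c(10, 10),
                                 amplitude = c(1, 3)))
  expect_equal(characterize_element(two, cyc)$gamma_frequency, 85)
  wrap <- list(cells = data.frame(row = c(10, 10), col = c(36, 1),
                                  amplitude = c(1, 1)))
  expect_equal(characterize_element(wrap, cyc)$gamma_phase, 0,
               tolerance = 1e-9)
})

test_that("table compilation trims amplitude tails and fast-running cycles", {
  set.seed(5)
  tab <- toy_element_table(n = 1000)
  tab$trial <- 1
  tab$gamma_amplitude <- runif(1000)
  out <- compile_element_table(tab)
  expect_gte(nrow(out), 980 - 20)
  expect_lte(nrow(out), 980)
  q <- quantile(tab$gamma_amplitude, c(0.01, 0.99))
  expect_true(all(out$gamma_amplitude > q[1] & out$gamma_amplitude < q[2]))
  tab2 <- tab
  tab2$speed[1:50] <- 120
  out2 <- compile_element_table(tab2)
  expect_true(all(out2$speed <= 100))
  empty <- compile_element_table(tab[0, ])
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "element_table")
})

test_that("gamma band ratio is signed by the slow/medium mass balance", {
  freqs <- seq(15, 200, 5)
  d40 <- as.numeric(freqs == 40)
  expect_equal(gamma_band_ratio(d40, freqs)$ratio, -1)
  d80 <- as.numeric(freqs == 80)
  expect_equal(gamma_band_ratio(d80, freqs)$ratio, 1)
  deq <- (freqs == 40) * 0.5 + (freqs == 80) * 0.5
  expect_equal(gamma_band_ratio(deq, freqs)$ratio, 0)
  expect_error(gamma_band_ratio(as.numeric(freqs == 150), freqs), "band")
})

test_that("KL bootstrap separates distinct distributions and not a null", {
  set.seed(6)
  a <- rnorm(3000, 40, 5)
  b <- rnorm(3000, 90, 5)
  res <- compare_distributions_kl(a, b, reps = 200, subsample = 500)
  expect_true(res$significant)
  same <- compare_distributions_kl(rnorm(3000, 60, 10), rnorm(3000, 60, 10),
                                   reps = 200, subsample = 500)
  expect_false(same$significant)
  ident <- compare_distributions_kl(a, a, reps = 100, subsample = 500)
  expect_lt(ident$divergence, res$divergence / 10)
  expect_lt(ident$divergence, 0.1)
})

test_that("per-cycle element counts never exceed four", {
  set.seed(7)
  for (i in 1:15) {
    m <- matrix(runif(38 * 36), 38, 36)
    p <- detect_patches(m, min_row_freq = NULL)
    expect_lte(length(p), 4)
    expect_gte(length(p), 1)
  }
})
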