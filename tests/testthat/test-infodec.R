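test_that("quartile discretization follows lower-closed edges with ties down", {
  expect_equal(as.integer(discretize_quartiles(1:8)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  set.seed(1)
  x <- rnorm(400)
  lab <- discretize_quartiles(x)
  expect_equal(unname(table(lab)), rep(100L, 4), ignore_attr = TRUE)
  expect_error(discretize_quartiles(rep(3, 20)), "constant")
  expect_error(discretize_quartiles(rnorm(5)))
})

test_that("discretization is invariant to monotone transforms", {
  set.seed(2)
  x <- rexp(200)
  expect_equal(as.integer(discretize_quartiles(x)),
               as.integer(discretize_quartiles(log(x))))
  expect_equal(as.integer(discretize_quartiles(x)),
               as.integer(discretize_quartiles(rank(x))))
})

test_that("mutual information behaves at the independence and identity poles", {
  set.seed(3)
  n <- 4000
  f <- sample(1:4, n, TRUE)
  g <- sample(1:4, n, TRUE)
  L <- factor(sample(letters[1:4], n, TRUE))
  ind <- mutual_information_pair(f, g, L)
  # plug-in bias bound: (cells-1)/(2 n ln 2) bits for 16x4 cells
  expect_lt(ind$bits, 2 * (16 * 4 - 1) / (2 * n * log(2)) + 0.02)
  idf <- mutual_information_pair(as.integer(L), g, L)
  expect_equal(idf$normalized, 1, tolerance = 0.02)
  # duplication leaves the plug-in estimate unchanged
  dup <- mutual_information_pair(c(f, f), c(g, g), c(L, L))
  expect_equal(dup$bits, ind$bits, tolerance = 1e-12)
  expect_error(mutual_information_pair(f[1:10], g, L), "length")
})

test_that("PID algebra reproduces the minimal-mutual-information identities", {
  parts <- pid_from_marginals(0.3, 0.5, 0.9)
  expect_equal(unname(parts["redundancy"]), 0.3)
  expect_equal(unname(parts["unique_f"]), 0)
  expect_equal(unname(parts["unique_g"]), 0.2)
  expect_equal(unname(parts["synergy"]), 0.4)
  expect_equal(sum(parts[c("unique_f", "unique_g", "redundancy",
                           "synergy")]), parts[["total"]])
})

test_that("identical sources are purely redundant; XOR is purely synergistic", {
  set.seed(4)
  f <- sample(1:4, 2000, TRUE)
  L <- factor(f)
  same <- pid_decompose(f, f, L)
  expect_equal(same$synergy, 0, tolerance = 1e-12)
  expect_equal(same$unique_f, 0, tolerance = 1e-12)
  expect_equal(same$unique_g, 0, tolerance = 1e-12)
  expect_equal(same$redundancy, same$total, tolerance = 1e-12)
  a <- sample(0:1, 4000, TRUE)
  b <- sample(0:1, 4000, TRUE)
  x <- pid_decompose(a, b, factor(a != b))
  expect_equal(x$redundancy, 0, tolerance = 0.01)
  expect_equal(x$synergy, x$total, tolerance = 0.01)
  expect_gt(x$total, 0.97)
})

test_that("PID parts are nonnegative and sum to the total on random tables", {
  set.seed(5)
  for (i in 1:20) {
    n <- 500
    f <- sample(1:4, n, TRUE)
    g <- (f + sample(0:2, n, TRUE)) %% 4 + 1
    L <- factor((g + sample(0:1, n, TRUE)) %% 4)
    p <- pid_decompose(f, g, L)
    expect_equal(p$unique_f + p$unique_g + p$redundancy + p$synergy,
                 p$total, tolerance = 1e-12)
    expect_gte(min(p$unique_f, p$unique_g), 0)
    expect_equal(min(p$unique_f, p$unique_g), 0, tolerance = 1e-12)
    expect_gte(p$redundancy, -1e-12)
  }
})

test_that("speed redundancy spans the independence-to-identity range", {
  set.seed(6)
  f <- sample(1:4, 3000, TRUE)
  v <- sample(1:4, 3000, TRUE)
  expect_lt(speed_redundancy(f, v), 0.02)
  expect_equal(speed_redundancy(f, f), 1)
  # 10% flipped labels: strictly between, matching a brute-force histogram
  g <- f
  flip <- sample(3000, 300)
  g[flip] <- sample(1:4, 300, TRUE)
  val <- speed_redundancy(f, g)
  expect_gt(val, 0.3)
  expect_lt(val, 1)
  tab <- table(f, g) / 3000
  brute <- sum(tab[tab > 0] * log2(tab[tab > 0] /
    outer(rowSums(tab), colSums(tab))[tab > 0])) /
    -sum(rowSums(tab) * log2(rowSums(tab)))
  expect_equal(val, brute, tolerance = 1e-12)
  expect_error(speed_redundancy(rep(1L, 100), v[1:100]), "entropy")
})

test_that("the pairwise PID table covers all 15 feature pairs", {
  tab <- toy_element_table(n = 400, shift = 30, seed = 7)
  pt <- pid_table(tab)
  expect_equal(nrow(pt), choose(6, 2))
  expect_true(all(pt$total >= 0))
  expect_true(all(abs(pt$unique_f + pt$unique_g + pt$redundancy +
                        pt$synergy - pt$total) < 1e-12))
})
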