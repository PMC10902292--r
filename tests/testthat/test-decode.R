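cfg_fast <- decoder_config(max_learners = 60, seed = 3)

test_that("separable classes are decoded nearly perfectly at resubstitution", {
  tab <- toy_element_table(n = 400, shift = 30, seed = 1)
  model <- train_location_classifier(tab, cfg_fast)
  expect_gt(cross_classify(model, tab), 0.95)
})

test_that("permuted labels decode at chance", {
  set.seed(2)
  tab <- toy_element_table(n = 400, shift = 30, seed = 1)
  tab$section <- sample(tab$section)
  rep0 <- evaluate_crossval(tab, cfg_fast, n_boot = 300)
  expect_gt(rep0$ci[2], rep0$chance - 0.02)
  expect_lt(rep0$overall, rep0$chance + 0.1)
})

test_that("training requires enough classes and cycles", {
  tab <- toy_element_table(n = 100, seed = 2)
  tab$section <- "other"
  expect_error(train_location_classifier(tab, cfg_fast), "2 classes")
  tab2 <- toy_element_table(n = 100, seed = 2)
  tab2 <- tab2[tab2$section != "other" | seq_len(100) <= 27, ]
  tab2$section[1:2] <- "rare"
  expect_error(train_location_classifier(tab2, cfg_fast), "rare")
})

test_that("cross-validation never splits a cycle between train and test", {
  tab <- toy_element_table(n = 200, seed = 3)
  rep0 <- evaluate_crossval(tab, cfg_fast, n_boot = 10)
  fold_per_cycle <- tapply(rep0$fold, paste(tab$trial, tab$cycle_id),
                           function(f) length(unique(f)))
  expect_true(all(fold_per_cycle == 1))
})

test_that("balanced undersampling decodes rare classes in imbalanced data", {
  set.seed(4)
  n <- 600
  section <- sample(c("common", "rare"), n, TRUE, prob = c(0.92, 0.08))
  tab <- data.frame(
    gamma_amplitude = rnorm(n), gamma_phase = runif(n, 0, 360),
    gamma_frequency = ifelse(section == "rare", 100, 50) + rnorm(n, 0, 5),
    theta_amplitude = rnorm(n), theta_frequency = rnorm(n, 8),
    theta_asymmetry = rnorm(n, 1, 0.1),
    section = section, cycle_id = seq_len(n), channel = 1)
  rep0 <- evaluate_crossval(tab, cfg_fast, n_boot = 10)
  expect_gt(rep0$per_class[["rare"]], 0.9)
  expect_gt(rep0$per_class[["common"]], 0.9)
})

test_that("decoding performance rises with modulation strength", {
  accs <- sapply(c(0, 15, 40), function(shift) {
    tab <- toy_element_table(n = 360, shift = shift, seed = 5)
    evaluate_crossval(tab, cfg_fast, n_boot = 10)$overall
  })
  expect_true(all(diff(accs) > 0))
})

test_that("reduced feature sets drop informative dimensions", {
  tab <- toy_element_table(n = 360, shift = 30, seed = 6)
  full <- evaluate_crossval(tab, cfg_fast, n_boot = 10)$overall
  theta_only <- evaluate_crossval(
    tab, decoder_config(max_learners = 60, feature_set = "theta", seed = 3),
    n_boot = 10)$overall
  gamma_only <- evaluate_crossval(
    tab, decoder_config(max_learners = 60, feature_set = "gamma", seed = 3),
    n_boot = 10)$overall
  # the signal lives in gamma frequency: theta-only must collapse to chance
  expect_gt(gamma_only, theta_only + 0.2)
  expect_gt(full, 0.6)
})

test_that("conditional performance partitions elements across quartiles", {
  tab <- toy_element_table(n = 400, shift = 30, seed = 7)
  rep0 <- evaluate_crossval(tab, cfg_fast, n_boot = 10)
  ns <- sapply(1:4, function(q)
    conditional_performance(rep0, tab, "gamma_amplitude", q)$n)
  expect_equal(sum(ns), sum(!is.na(rep0$predictions)))
})

test_that("cross-classification on the training table is resubstitution", {
  tab <- toy_element_table(n = 300, shift = 30, seed = 8)
  model <- train_location_classifier(tab, cfg_fast)
  direct <- mean(predict(model, tab) == tab$section)
  expect_equal(cross_classify(model, tab), direct)
  expect_error(cross_classify(model, tab[, 1:3]), "mismatch")
})

test_that("twin tables cross-decode; disjoint modulations do not", {
  tab_a <- toy_element_table(n = 400, shift = 30, seed = 9)
  tab_b <- toy_element_table(n = 400, shift = 30, seed = 10)
  model_a <- train_location_classifier(tab_a, cfg_fast)
  within_b <- evaluate_crossval(tab_b, cfg_fast, n_boot = 100)
  cross_ab <- cross_classify(model_a, tab_b)
  expect_gt(cross_ab, within_b$ci[1] - 0.1)
  # opposite modulation direction: cross performance collapses
  tab_c <- toy_element_table(n = 400, shift = -30, seed = 11)
  expect_lt(cross_classify(model_a, tab_c), 0.35)
})

test_that("learning windows follow cumulative counts and degenerate inputs", {
  w <- make_learning_windows(c(1000, 1000, 1000, 1000), target = 3000)
  expect_equal(w$windows$stop[1], 3)
  expect_equal(w$pivot, 3)
  w2 <- make_learning_windows(c(5000), target = 3000)
  expect_equal(nrow(w2$windows), 1)
  expect_equal(w2$windows$stop, 1)
  # no two consecutive windows share both endpoints
  w3 <- make_learning_windows(rep(800, 10), target = 3000)
  key <- paste(w3$windows$start, w3$windows$stop)
  expect_false(any(duplicated(key)))
})

test_that("cross-matrix asymmetry and block means behave as defined", {
  m <- matrix(0.45, 4, 4)
  expect_equal(asymmetry_and_improvement(m)$asymmetry_pct, 0)
  m2 <- matrix(0.4, 4, 4)
  m2[upper.tri(m2)] <- 0.5
  expect_equal(asymmetry_and_improvement(m2)$asymmetry_pct, 25)
  expect_error(asymmetry_and_improvement(matrix(1, 1, 1)), "square")
  # block structure with the 3/4 membership rule
  mb <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  layers <- rbind(rep("rad", 4), rep("rad", 4),
                  c("l-m", "l-m", "l-m", "rad"),  # 3/4 l-m: counts as l-m
                  c("l-m", "l-m", "rad", "rad")) # 2/4: excluded
  res <- asymmetry_and_improvement(mb, layers)
  expect_equal(res$block_means["rad", "rad"], 1)
  expect_equal(res$block_means["l-m", "l-m"], 1)
  expect_equal(res$block_means["rad", "l-m"], 0)
  expect_equal(res$block_channels$`l-m`, 3)
})
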