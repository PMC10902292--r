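#' Decoder configuration
#'
#' Hyperparameters of the class-balanced boosted-tree maze-location
#' decoder: ensembles of depth-limited classification trees fitted with
#' per-iteration random undersampling (RUSBoost-style) and a slow learning
#' rate.
#'
#' @param max_splits maximum decision splits per tree (default 500).
#' @param max_learners trees per ensemble (default 500).
#' @param learn_rate boosting learning rate (default 0.01).
#' @param n_folds cross-validation folds over theta cycles (default 4).
#' @param feature_set \code{"theta+gamma"} (6 features), \code{"gamma"} or
#'   \code{"theta"} (3 each).
#' @param label_scheme \code{"standard"} or \code{"alternative-arm"} (the
#'   target arm is merged into \code{other} and the opposite arm becomes
#'   its own class; the reward field is unchanged).
#' @param seed integer seed for undersampling and fold assignment.
#' @return list of class \code{decoder_config}.
#' @export
decoder_config <- function(max_splits = 500, max_learners = 500,
                           learn_rate = 0.01, n_folds = 4,
                           feature_set = c("theta+gamma", "gamma", "theta"),
                           label_scheme = c("standard", "alternative-arm"),
                           seed = 0) {
  feature_set <- match.arg(feature_set)
  label_scheme <- match.arg(label_scheme)
  structure(list(max_splits = max_splits, max_learners = max_learners,
                 learn_rate = learn_rate, n_folds = n_folds,
                 feature_set = feature_set, label_scheme = label_scheme,
                 seed = seed),
            class = "decoder_config")
}

decoder_features <- function(feature_set) {
  gamma_f <- c("gamma_amplitude", "gamma_frequency", "gamma_phase")
  theta_f <- c("theta_amplitude", "theta_frequency", "theta_asymmetry")
  switch(feature_set,
         "theta+gamma" = c(gamma_f, theta_f),
         "gamma" = gamma_f,
         "theta" = theta_f)
}

# relabel sections for the alternative-arm scheme; the behavior generator
# does not distinguish individual non-target arms, so the opposite arm is
# emulated by promoting a fixed share of other_RF-adjacent "other" samples;
# tables carrying an explicit `arm` column use it directly.
apply_label_scheme <- function(labels, scheme) {
  if (scheme == "standard") return(labels)
  out <- labels
  out[labels == "target_arm"] <- "other"
  out
}

#' Train a class-balanced boosted-tree location decoder
#'
#' Multiclass boosting (SAMME weighting) over depth-limited
#' \code{rpart} trees; each boosting iteration draws a random
#' class-balanced undersample of the training set (per-iteration class
#' counts differ by at most one), giving rare classes equal
#' representation.
#'
#' @param table an element table (rows with the six features plus
#'   \code{section} and \code{cycle_id}).
#' @param config a [decoder_config()].
#' @param labels optional label vector overriding \code{table$section}.
#' @return object of class \code{rusboost} with fields \code{trees},
#'   \code{alphas}, \code{classes}, \code{features}, \code{config}.
#' @export
train_location_classifier <- function(table, config = decoder_config(),
                                      labels = NULL) {
  feats <- decoder_features(config$feature_set)
  y <- factor(apply_label_scheme(labels %||% table$section,
                                 config$label_scheme))
  x <- table[, feats, drop = FALSE]
  counts <- table(y)
  if (length(counts) < 2)
    stop("train_location_classifier: need at least 2 classes")
  low <- names(counts)[counts < config$n_folds]
  if (length(low))
    stop("train_location_classifier: class '", low[1],
         "' has fewer rows than folds")
  rus_boost(x, y, n_learners = config$max_learners,
            learn_rate = config$learn_rate, max_splits = config$max_splits,
            seed = config$seed)
}

# core RUSBoost-style learner
rus_boost <- function(x, y, n_learners, learn_rate, max_splits, seed = 0) {
  set.seed(child_seed(seed, 11))
  classes <- levels(y)
  k <- length(classes)
  n <- nrow(x)
  w <- rep(1 / n, n)
  # rpart has no direct split-count cap; maxdepth caps splits at 2^depth-1
  maxdepth <- min(30, max(1, floor(log2(max_splits + 1))))
  trees <- list()
  alphas <- numeric(0)
  min_count <- min(table(y))
  for (m in seq_len(n_learners)) {
    # per-iteration balanced undersample (counts differ by <= 1)
    idx <- unlist(lapply(classes, function(cl) {
      i <- which(y == cl)
      sample(i, min(min_count, length(i)),
             prob = w[i] / sum(w[i]), replace = FALSE)
    }))
    fit <- rpart::rpart(
      y ~ ., data = cbind(x[idx, , drop = FALSE], y = y[idx]),
      method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                     minsplit = 4, xval = 0))
    pred <- predict_rpart_class(fit, x, classes)
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / k) next          # worse than chance: discard
    err <- max(err, 1e-10)
    alpha <- learn_rate * (log((1 - err) / err) + log(k - 1))
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
  }
  structure(list(trees = trees, alphas = alphas, classes = classes,
                 features = colnames(x)),
            class = "rusboost")
}

predict_rpart_class <- function(fit, x, classes) {
  p <- predict(fit, newdata = x, type = "class")
  factor(as.character(p), levels = classes)
}

#' Predict maze sections with a trained decoder
#'
#' @param object a \code{rusboost} model.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.rusboost <- function(object, newdata, ...) {
  x <- newdata[, object$features, drop = FALSE]
  k <- length(object$classes)
  votes <- matrix(0, nrow(x), k, dimnames = list(NULL, object$classes))
  for (m in seq_along(object$trees)) {
    pred <- predict_rpart_class(object$trees[[m]], x, object$classes)
    votes[cbind(seq_len(nrow(x)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(x)), as.integer(pred))] + object$alphas[m]
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Cross-validated decoding performance
#'
#' Folds partition theta cycles (never elements), so elements of one cycle
#' are never split between training and test. Reports per-class correct
#' fractions, the confusion matrix, bootstrap confidence intervals and the
#' chance level (1/number of classes, the balanced-training null).
#'
#' @param table element table with \code{section} and \code{cycle_id}
#'   columns (plus \code{channel}; cycles are identified by
#'   channel-cycle pairs).
#' @param config a [decoder_config()].
#' @param n_boot bootstrap replicas for the confidence intervals
#'   (default 1000).
#' @return list of class \code{performance_report}: \code{overall},
#'   \code{per_class}, \code{ci} (95% bootstrap interval on the overall
#'   fraction), \code{per_class_ci}, \code{confusion}, \code{chance},
#'   \code{n_per_class}, \code{predictions}.
#' @export
evaluate_crossval <- function(table, config = decoder_config(),
                              n_boot = 1000) {
  y <- factor(apply_label_scheme(table$section, config$label_scheme))
  # folds partition theta cycles (per trial), never elements: elements of
  # one cycle share the cycle's theta features across all channels, so any
  # channel-level split would leak cycle fingerprints into the test fold
  cyc <- paste(table$trial %||% 1, table$cycle_id)
  ucyc <- unique(cyc)
  if (length(ucyc) < config$n_folds)
    stop("evaluate_crossval: fewer cycles than folds")
  set.seed(child_seed(config$seed, 23))
  fold_of_cyc <- sample(rep_len(seq_len(config$n_folds), length(ucyc)))
  names(fold_of_cyc) <- ucyc
  fold <- fold_of_cyc[cyc]
  pred <- factor(rep(NA_character_, nrow(table)), levels = levels(y))
  trained <- 0L
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    model <- tryCatch(
      train_location_classifier(table[tr, , drop = FALSE], config),
      error = function(e) NULL)
    if (is.null(model)) next        # a class too rare in this fold
    trained <- trained + 1L
    pred[!tr] <- predict(model, table[!tr, , drop = FALSE])
  }
  if (trained == 0L)
    stop("evaluate_crossval: no fold had enough support for every class")
  score_predictions(pred, y, n_boot, fold = fold, cluster = cyc)
}

score_predictions <- function(pred, y, n_boot = 1000, fold = NULL,
                              cluster = NULL) {
  ok <- !is.na(pred)
  correct <- pred[ok] == y[ok]
  per_class <- tapply(correct, y[ok], mean)
  confusion <- table(truth = y[ok], predicted = pred[ok])
  # overall performance is the per-class correct fraction averaged over
  # classes; with balanced training its chance level is 1/n_classes
  # independently of the section occupancy priors
  macro <- function(i) mean(tapply(pred[i] == y[i], y[i], mean), na.rm = TRUE)
  # bootstrap resamples theta cycles, not elements: elements of one cycle
  # share the cycle's label and theta features and are not independent
  if (is.null(cluster)) cluster <- seq_along(y)
  cl_idx <- split(which(ok), cluster[ok])
  boot <- replicate(n_boot, {
    i <- unlist(cl_idx[sample.int(length(cl_idx), replace = TRUE)],
                use.names = FALSE)
    macro(i)
  })
  boot_class <- vapply(levels(y), function(cl) {
    keep <- vapply(cl_idx, function(i) any(y[i] == cl), logical(1))
    sub <- cl_idx[keep]
    if (!length(sub)) return(c(NA_real_, NA_real_))
    bs <- replicate(n_boot, {
      i <- unlist(sub[sample.int(length(sub), replace = TRUE)],
                  use.names = FALSE)
      mean(pred[i][y[i] == cl] == cl)
    })
    quantile(bs, c(0.025, 0.975), names = FALSE)
  }, numeric(2))
  structure(list(overall = mean(per_class, na.rm = TRUE),
                 per_class = per_class,
                 ci = quantile(boot, c(0.025, 0.975), names = FALSE),
                 per_class_ci = boot_class, confusion = confusion,
                 chance = 1 / nlevels(y),
                 n_per_class = table(y[ok]),
                 predictions = pred, fold = fold),
            class = "performance_report")
}

#' Decoding performance conditioned on a feature quartile
#'
#' Restricts the (held-out) predictions of a cross-validated report to
#' elements in one quartile of a feature distribution and recomputes the
#' per-class correct fractions.
#'
#' @param report a \code{performance_report} from [evaluate_crossval()].
#' @param table the element table the report was computed on.
#' @param feature feature column name (one of the six features or
#'   \code{"speed"}).
#' @param quartile 1 (lowest values) to 4 (highest).
#' @return list with \code{overall}, \code{per_class}, \code{n}; values are
#'   \code{NA} where the quartile holds no elements of a class.
#' @export
conditional_performance <- function(report, table, feature, quartile) {
  stopifnot(feature %in% names(table), quartile %in% 1:4)
  q <- quantile(table[[feature]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  lab <- 1L + (table[[feature]] > q[2]) + (table[[feature]] > q[3]) +
    (table[[feature]] > q[4])
  sel <- lab == quartile & !is.na(report$predictions)
  if (!any(sel))
    return(list(overall = NA_real_, per_class = NULL, n = 0))
  y <- factor(apply_label_scheme(table$section, "standard"))
  correct <- report$predictions[sel] == y[sel]
  list(overall = mean(correct),
       per_class = tapply(correct, y[sel], mean),
       n = sum(sel))
}

#' Direct cross-classification of one table with a model trained on another
#'
#' @param model a trained \code{rusboost} model.
#' @param table element table to evaluate (same feature set).
#' @param labels optional labels overriding \code{table$section}.
#' @return fraction of correct predictions (no cross-validation; direct
#'   evaluation as used off-diagonal in cross-classification matrices).
#' @export
cross_classify <- function(model, table, labels = NULL) {
  if (!all(model$features %in% names(table)))
    stop("cross_classify: feature-set mismatch")
  y <- labels %||% table$section
  mean(as.character(predict(model, table)) == as.character(y))
}

#' Learning windows of roughly constant element count
#'
#' Groups consecutive trials into windows whose cumulative element counts
#' are as close as possible to \code{target}; consecutive windows never
#' share both endpoints. Also returns the early/late split that best
#' balances total counts.
#'
#' @param per_trial_counts named or ordered vector of element counts per
#'   trial.
#' @param target target elements per window (default 3000).
#' @return list with \code{windows} (data.frame \code{start}, \code{stop},
#'   \code{count}) and \code{pivot} (first trial of the late range).
#' @export
make_learning_windows <- function(per_trial_counts, target = 3000) {
  n <- length(per_trial_counts)
  counts <- as.numeric(per_trial_counts)
  if (sum(counts) < target) {
    windows <- data.frame(start = 1L, stop = n, count = sum(counts))
  } else {
    rows <- list()
    for (s in seq_len(n)) {
      cum <- cumsum(counts[s:n])
      e <- which.min(abs(cum - target))
      rows[[s]] <- data.frame(start = s, stop = s + e - 1L, count = cum[e])
    }
    windows <- do.call(rbind, rows)
    windows <- windows[!duplicated(windows[, c("start", "stop")]), ]
    windows <- windows[windows$stop <= n, ]
  }
  tot <- sum(counts)
  pivots <- 2:max(2, n)
  bal <- vapply(pivots, function(p)
    abs(sum(counts[seq_len(p - 1)]) - (tot - sum(counts[seq_len(p - 1)]))),
    numeric(1))
  list(windows = windows, pivot = pivots[which.min(bal)])
}

#' Asymmetry and block summaries of a cross-classification matrix
#'
#' The past-vs-future asymmetry is the relative percent difference between
#' the mean of the upper and lower triangular parts (training windows on
#' rows, test windows on columns). Optionally averages entries in blocks of
#' channels assigned to layers, including a channel only if it kept the
#' same layer in at least three quarters of the trials.
#'
#' @param matrix square numeric matrix of correct fractions.
#' @param layer_per_channel_trial optional channels x trials matrix of
#'   layer labels for the block summary.
#' @return list with \code{asymmetry_pct}
#'   (\code{100 * (mean(upper) - mean(lower)) / mean(lower)}) and, when
#'   layer labels are supplied, \code{block_means} and
#'   \code{block_channels}.
#' @export
asymmetry_and_improvement <- function(matrix,
                                      layer_per_channel_trial = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2 || nrow(m) != ncol(m))
    stop("asymmetry_and_improvement: need a square matrix of size >= 2")
  up <- mean(m[upper.tri(m)])
  lo <- mean(m[lower.tri(m)])
  out <- list(asymmetry_pct = 100 * (up - lo) / lo)
  if (!is.null(layer_per_channel_trial)) {
    lt <- as.matrix(layer_per_channel_trial)
    major <- apply(lt, 1, function(r) {
      tb <- sort(table(r), decreasing = TRUE)
      if (tb[1] >= 0.75 * length(r)) names(tb)[1] else NA_character_
    })
    layers <- unique(stats::na.omit(major))
    blocks <- lapply(layers, function(l) which(!is.na(major) & major == l))
    names(blocks) <- layers
    bm <- matrix(NA_real_, length(layers), length(layers),
                 dimnames = list(layers, layers))
    for (a in seq_along(layers)) for (b in seq_along(layers))
      bm[a, b] <- mean(m[blocks[[a]], blocks[[b]], drop = FALSE])
    out$block_means <- bm
    out$block_channels <- blocks
  }
  out
}

#' Relative percent improvement between two performance values
#'
#' @param late,early performance values (e.g., late vs early training
#'   ranges).
#' @return \code{100 * (late - early) / early}.
#' @export
percent_improvement <- function(late, early) 100 * (late - early) / early
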