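#' Fit a probabilistic neural network (Parzen kernel Bayes classifier)
#'
#' Stores the training patterns per class. Prediction scores a query `x`
#' against class `c` as `prior_c * mean_i exp(-||x - x_i||^2 / (2 sigma^2))`
#' over the class-c patterns (the pattern and summation layers of the
#' classical four-layer network); the predicted label is the arg-max, ties
#' broken toward the lowest class id. Scores are compared in the log domain so
#' the nearest-neighbour limit `sigma -> 0` is numerically exact.
#'
#' @param train Feature table data frame with `label`, or numeric matrix plus
#'   `labels`.
#' @param sigma Kernel spread (> 0). Default 0.1, suited to features scaled
#'   into \[0, 1\].
#' @param priors `"uniform"` (default) or `"empirical"` class priors.
#' @param labels Class labels when `train` is a matrix.
#'
#' @return An object of class `pnn_model`.
#' @export
pnn_fit <- function(train, sigma = 0.1, priors = c("uniform", "empirical"),
                    labels = NULL) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  priors <- match.arg(priors)
  x <- feature_matrix(train)
  if (is.null(labels)) {
    if (!is.data.frame(train) || !"label" %in% names(train)) {
      stop("supply 'labels' or a table with a 'label' column", call. = FALSE)
    }
    labels <- train$label
  }
  cls <- sort(unique(labels))
  prior <- if (priors == "uniform") {
    rep(1 / length(cls), length(cls))
  } else {
    as.numeric(table(factor(labels, levels = cls))) / length(labels)
  }
  structure(
    list(patterns = x, labels = labels, classes = cls, prior = prior,
         sigma = sigma, feature_names = colnames(x)),
    class = "pnn_model"
  )
}

#' Predict class labels with a fitted PNN
#'
#' @param model A [pnn_fit()] result.
#' @param newdata Feature table or matrix with the training feature schema.
#' @return Vector of predicted class labels (same type as the training labels).
#' @export
pnn_predict <- function(model, newdata) {
  stopifnot(inherits(model, "pnn_model"))
  x <- feature_matrix(newdata)
  if (!is.null(model$feature_names)) {
    if (!all(model$feature_names %in% colnames(x))) {
      stop("newdata is missing training features", call. = FALSE)
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  tr <- model$patterns
  inv2s2 <- 1 / (2 * model$sigma^2)
  # squared distances query x training
  d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * tcrossprod(x, tr)
  d2[d2 < 0] <- 0
  loglik <- -d2 * inv2s2
  out <- vapply(seq_len(nrow(x)), function(i) {
    ll <- loglik[i, ]
    shift <- max(ll)
    scores <- vapply(seq_along(model$classes), function(k) {
      idx <- model$labels == model$classes[k]
      log(model$prior[k]) + shift + log(mean(exp(ll[idx] - shift)))
    }, numeric(1))
    which.max(scores)  # ties -> lowest class id (classes sorted ascending)
  }, integer(1))
  model$classes[out]
}

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param mtry Candidate features per split; `NULL` (default) applies the
#'   `round(sqrt(p))` rule to the training table at fit time (4 for the
#'   paper-scale 15/16-feature subsets).
#' @param seed Integer seed making the forest reproducible.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100L, mtry = NULL, seed = 1L) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("'n_trees' must be >= 1", call. = FALSE)
  if (!is.null(mtry) && (mtry < 1L)) stop("'mtry' must be >= 1", call. = FALSE)
  structure(list(n_trees = n_trees, mtry = mtry, seed = as.integer(seed)),
            class = "rf_config")
}

#' Default mtry rule
#'
#' @param p Number of features.
#' @return `max(1, round(sqrt(p)))`.
#' @export
default_mtry <- function(p) max(1L, as.integer(round(sqrt(p))))

#' Fit a bagged-CART random forest
#'
#' Thin, protocol-preserving wrapper around [randomForest::randomForest()]:
#' bootstrap resamples of size n, unpruned trees grown to purity
#' (`nodesize = 1`), `mtry` random candidate features per node, majority-vote
#' prediction, fully seeded.
#'
#' @param train Feature table with `label`, or matrix plus `labels`.
#' @param cfg An [rf_config()].
#' @param labels Class labels when `train` is a matrix.
#' @return An object of class `odor_rf` wrapping the forest.
#' @export
rf_fit <- function(train, cfg = rf_config(), labels = NULL) {
  stopifnot(inherits(cfg, "rf_config"))
  x <- feature_matrix(train)
  if (is.null(labels)) {
    if (!is.data.frame(train) || !"label" %in% names(train)) {
      stop("supply 'labels' or a table with a 'label' column", call. = FALSE)
    }
    labels <- train$label
  }
  if (length(unique(labels)) < 2L) {
    warning("single-class training data: constant predictor")
    return(structure(list(constant = unique(labels)[1L],
                          feature_names = colnames(x)),
                     class = "odor_rf"))
  }
  mtry <- if (is.null(cfg$mtry)) default_mtry(ncol(x)) else min(cfg$mtry, ncol(x))
  set.seed(cfg$seed)
  forest <- randomForest::randomForest(
    x = x, y = factor(labels), ntree = cfg$n_trees, mtry = mtry,
    replace = TRUE, nodesize = 1
  )
  structure(list(forest = forest, feature_names = colnames(x), mtry = mtry),
            class = "odor_rf")
}

#' Predict class labels with a fitted forest
#'
#' @param model An [rf_fit()] result.
#' @param newdata Feature table or matrix with the training feature schema.
#' @return Vector of predicted labels (training label type).
#' @export
rf_predict <- function(model, newdata) {
  stopifnot(inherits(model, "odor_rf"))
  x <- feature_matrix(newdata)
  if (!is.null(model$constant)) {
    return(rep(model$constant, nrow(x)))
  }
  if (!all(model$feature_names %in% colnames(x))) {
    stop("newdata is missing training features", call. = FALSE)
  }
  x <- x[, model$feature_names, drop = FALSE]
  pred <- stats::predict(model$forest, x)
  lv <- levels(model$forest$y)
  out <- lv[as.integer(pred)]
  if (!anyNA(suppressWarnings(as.numeric(lv)))) out <- as.numeric(out)
  out
}

#' Classification accuracy in percent
#'
#' @param predicted,truth Equal-length label vectors.
#' @return `100 * #matches / n`.
#' @export
accuracy <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must be non-empty and of equal length",
         call. = FALSE)
  }
  100 * mean(predicted == truth)
}

derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' Wrapper evaluation of nested feature subsets
#'
#' For every subset, restricts the (already normalized) feature table to those
#' features, trains each classifier on the training partition and reports the
#' test accuracy, averaging the (stochastic) random forest over `n_repeats`
#' seeded repetitions. The PNN is deterministic so its repeats collapse to
#' one run.
#'
#' @param table Normalized feature table (`sample_id`, `label`, features).
#' @param subsets Named list of feature-name vectors, e.g. [nested_subsets()].
#' @param split A [kennard_stone()] split (indices into `table` rows).
#' @param n_repeats RF repetitions per subset (default 10).
#' @param n_trees,mtry Forest settings; `mtry = NULL` applies the
#'   `round(sqrt(k))` per-subset rule.
#' @param sigma PNN spread.
#' @param seed Master seed for the RF repetitions.
#'
#' @return An object of class `subset_evaluation`: data frame with `subset`,
#'   `n_features`, `rf_acc`, `pnn_acc` (percent), with attributes `best_rf`
#'   and `best_pnn` giving the arg-max subset index (ties toward the smaller
#'   subset).
#' @export
evaluate_subsets <- function(table, subsets, split, n_repeats = 10L,
                             n_trees = 100L, mtry = NULL, sigma = 0.1,
                             seed = 1L) {
  stopifnot(inherits(split, "split_indices"))
  feats <- feature_columns(table)
  unknown <- setdiff(unique(unlist(subsets)), feats)
  if (length(unknown)) {
    stop("unknown feature(s) in subsets: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  train <- table[split$train, , drop = FALSE]
  test <- table[split$test, , drop = FALSE]
  seeds <- derive_seeds(seed, n_repeats * length(subsets))
  rows <- lapply(seq_along(subsets), function(i) {
    keep <- c("sample_id", "label", subsets[[i]])
    tr <- train[, keep, drop = FALSE]
    te <- test[, keep, drop = FALSE]
    rf_accs <- vapply(seq_len(n_repeats), function(r) {
      cfg <- rf_config(n_trees, mtry, seeds[(i - 1L) * n_repeats + r])
      accuracy(rf_predict(rf_fit(tr, cfg), te), te$label)
    }, numeric(1))
    pnn <- pnn_fit(tr, sigma = sigma)
    data.frame(subset = i, n_features = length(subsets[[i]]),
               rf_acc = mean(rf_accs),
               pnn_acc = accuracy(pnn_predict(pnn, te), te$label))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "best_rf") <- which.max(out$rf_acc)   # ties -> smaller subset
  attr(out, "best_pnn") <- which.max(out$pnn_acc)
  class(out) <- c("subset_evaluation", "data.frame")
  out
}

#' Random-forest tree-count sweep
#'
#' Sweeps the forest size over `tree_counts` (default 2 to 100 in steps of
#' two), averaging training and testing accuracy over `n_repeats` seeded
#' forests per count, and summarizes the stabilization point: the smallest
#' count from which every later mean test accuracy stays within `stable_tol`
#' percentage points of the final value.
#'
#' @param table Normalized feature table.
#' @param split A [kennard_stone()] split.
#' @param mtry Forest mtry (`NULL` for the `round(sqrt(p))` rule).
#' @param tree_counts Grid of forest sizes.
#' @param n_repeats Seeded repetitions per count (default 100).
#' @param stable_tol Stabilization band in percentage points (default 5).
#' @param seed Master seed.
#'
#' @return Data frame with `n_trees`, `train_acc`, `test_acc`, with attribute
#'   `stable_from` (the stabilization tree count).
#' @export
tree_sweep <- function(table, split, mtry = NULL,
                       tree_counts = seq(2L, 100L, by = 2L),
                       n_repeats = 100L, stable_tol = 5, seed = 1L) {
  stopifnot(inherits(split, "split_indices"), length(tree_counts) >= 1L)
  train <- table[split$train, , drop = FALSE]
  test <- table[split$test, , drop = FALSE]
  seeds <- derive_seeds(seed, n_repeats * length(tree_counts))
  rows <- lapply(seq_along(tree_counts), function(i) {
    acc <- vapply(seq_len(n_repeats), function(r) {
      cfg <- rf_config(tree_counts[i], mtry,
                       seeds[(i - 1L) * n_repeats + r])
      fit <- rf_fit(train, cfg)
      c(accuracy(rf_predict(fit, train), train$label),
        accuracy(rf_predict(fit, test), test$label))
    }, numeric(2))
    data.frame(n_trees = tree_counts[i],
               train_acc = mean(acc[1L, ]), test_acc = mean(acc[2L, ]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  final <- out$test_acc[nrow(out)]
  within <- abs(out$test_acc - final) <= stable_tol
  stable_idx <- Position(function(i) all(within[i:length(within)]),
                         seq_along(within))
  attr(out, "stable_from") <- out$n_trees[stable_idx]
  out
}
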