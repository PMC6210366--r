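# Coerce a feature table (or plain matrix/data.frame of numerics) to the
# numeric feature matrix used by the multivariate routines.
feature_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  feats <- feature_columns(table)
  m <- as.matrix(table[, feats, drop = FALSE])
  rownames(m) <- if ("sample_id" %in% names(table)) table$sample_id else NULL
  m
}

#' Fit a principal component analysis on a feature table
#'
#' Covariance-based PCA (centering only) by default, matching features that
#' were already min-max scaled upstream; correlation-based PCA is available
#' via `scale. = TRUE`.
#'
#' @param table Feature table data frame or numeric matrix.
#' @param scale. Autoscale columns before the decomposition (default `FALSE`).
#'
#' @return An object of class `odor_pca` wrapping the loadings, the
#'   per-component explained-variance percentages and the centering/scaling
#'   parameters.
#' @export
pca_fit <- function(table, scale. = FALSE) {
  x <- feature_matrix(table)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ratios <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(loadings = fit$rotation, explained = ratios,
         center = fit$center, scale = fit$scale, sdev = fit$sdev),
    class = "odor_pca"
  )
}

#' Project a feature table onto retained principal components
#'
#' Retains either an explicit number of components `k` or the smallest number
#' whose cumulative explained variance reaches `cumulative` percent.
#'
#' @param model A [pca_fit()] result.
#' @param table Table to project (same features as the fit).
#' @param k Explicit component count (overrides `cumulative` when given).
#' @param cumulative Cumulative explained-variance cutoff in percent
#'   (default 99).
#'
#' @return Data frame with `sample_id`, `label` (when present in `table`) and
#'   score columns `PC1..PCk`.
#' @export
pca_reduce <- function(model, table, k = NULL, cumulative = 99) {
  stopifnot(inherits(model, "odor_pca"))
  x <- feature_matrix(table)
  if (is.null(k)) {
    k <- which(cumsum(model$explained) >= cumulative)[1L]
    if (is.na(k)) k <- length(model$explained)
  }
  k <- as.integer(k)
  if (k < 1L || k > ncol(model$loadings)) {
    stop("'k' must be between 1 and ", ncol(model$loadings), call. = FALSE)
  }
  x <- sweep(x, 2L, model$center, "-")
  if (!isFALSE(model$scale[1L]) && !is.null(names(model$scale))) {
    x <- sweep(x, 2L, model$scale, "/")
  }
  scores <- x %*% model$loadings[, seq_len(k), drop = FALSE]
  out <- as.data.frame(scores)
  names(out) <- paste0("PC", seq_len(k))
  if (is.data.frame(table) && all(c("sample_id", "label") %in% names(table))) {
    out <- cbind(table[, c("sample_id", "label")], out)
  }
  rownames(out) <- NULL
  out
}

one_hot <- function(labels) {
  f <- factor(labels)
  y <- matrix(0, nrow = length(labels), ncol = nlevels(f),
              dimnames = list(NULL, levels(f)))
  y[cbind(seq_along(labels), as.integer(f))] <- 1
  y
}

#' Fit a PLS2 model by NIPALS
#'
#' Partial least squares of a (column-centered, optionally autoscaled)
#' predictor matrix against a one-hot class indicator matrix (PLS-DA).
#' Each component extracts a unit-norm weight vector `w_a`, scores
#' `t_a = X w_a`, response loadings `q_a`, then deflates both blocks.
#'
#' @param X Feature table data frame or numeric matrix.
#' @param labels Class labels (one per row); alternatively pass a numeric
#'   response matrix via `Y`.
#' @param A Number of components (default `nlevels - 1`).
#' @param scale. Autoscale X columns (default `FALSE`; features are normally
#'   min-max scaled upstream).
#' @param Y Optional explicit response matrix overriding `labels`.
#' @param tol,max_iter NIPALS convergence controls.
#'
#' @return An object of class `pls2_model` with weights `W` (p x A, unit
#'   columns), scores `T`, X loadings `P`, Y loadings `Q`, per-component
#'   explained Y-variance `ssy`, and the centering parameters.
#' @export
pls2_fit <- function(X, labels = NULL, A = NULL, scale. = FALSE, Y = NULL,
                     tol = 1e-12, max_iter = 500L) {
  x <- feature_matrix(X)
  if (is.null(Y)) {
    if (is.null(labels) && is.data.frame(X) && "label" %in% names(X)) {
      labels <- X$label
    }
    if (is.null(labels)) stop("supply 'labels' or 'Y'", call. = FALSE)
    if (length(unique(labels)) < 2L) {
      stop("PLS-DA needs at least 2 classes", call. = FALSE)
    }
    Y <- one_hot(labels)
  }
  if (is.null(A)) A <- max(1L, ncol(Y) - 1L)
  A <- as.integer(A)
  n <- nrow(x); p <- ncol(x)
  if (A < 1L) stop("'A' must be >= 1", call. = FALSE)
  if (A > min(n - 1L, p)) {
    stop("'A' must be <= min(n - 1, p) = ", min(n - 1L, p), call. = FALSE)
  }
  x_center <- colMeans(x)
  Xc <- sweep(x, 2L, x_center, "-")
  x_scale <- rep(1, p)
  if (scale.) {
    x_scale <- apply(Xc, 2L, stats::sd)
    if (any(x_scale == 0)) {
      stop("zero-variance feature; cannot autoscale", call. = FALSE)
    }
    Xc <- sweep(Xc, 2L, x_scale, "/")
  }
  if (all(abs(Xc) < .Machine$double.eps)) {
    stop("X has no variance after centering", call. = FALSE)
  }
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_center, "-")

  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); Q <- matrix(0, ncol(Y), A)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    u <- Yc[, which.max(apply(Yc, 2L, stats::var))]
    w <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w_new <- drop(crossprod(Xc, u))
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) stop("degenerate PLS component ", a, call. = FALSE)
      w_new <- w_new / nw
      t_new <- drop(Xc %*% w_new)
      q <- drop(crossprod(Yc, t_new)) / sum(t_new^2)
      u_new <- drop(Yc %*% q) / sum(q^2)
      if (sum((w_new - w)^2) < tol) {
        w <- w_new
        break
      }
      w <- w_new
      u <- u_new
    }
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- drop(crossprod(Yc, t_a)) / tt
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a; Tm[, a] <- t_a
    ssy[a] <- sum(q_a^2) * tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    Yc <- Yc - tcrossprod(t_a, q_a)
  }
  rownames(W) <- rownames(P) <- colnames(x)
  structure(
    list(W = W, P = P, T = Tm, Q = Q, ssy = ssy, A = A,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         feature_names = colnames(x)),
    class = "pls2_model"
  )
}

#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP: `VIP_j = sqrt(p * sum_a ssy_a * w_ja^2 / sum_a ssy_a)` with
#' unit-norm component weights `w_a` and `ssy_a` the Y-variance explained by
#' component `a`. Satisfies `mean(VIP^2) = 1` by construction. Features are
#' ranked by descending score; ties break toward the earlier feature in table
#' order.
#'
#' @param model A fitted [pls2_fit()] model.
#' @return An object of class `vip_ranking`: a data frame with `feature`,
#'   `score`, `rank`, `above_one` (annotation only), sorted by rank.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls2_model"))
  if (all(model$ssy == 0)) {
    stop("degenerate model: no Y-variance explained", call. = FALSE)
  }
  W <- model$W
  p <- nrow(W)
  wnorm2 <- colSums(W^2)
  contrib <- sweep(W^2, 2L, wnorm2, "/")
  vip <- sqrt(p * drop(contrib %*% model$ssy) / sum(model$ssy))
  feats <- model$feature_names
  if (is.null(feats)) feats <- paste0("X", seq_len(p))
  ord <- order(-vip, seq_len(p))
  out <- data.frame(feature = feats[ord], score = vip[ord],
                    rank = seq_len(p), above_one = vip[ord] > 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("vip_ranking", "data.frame")
  out
}

#' Nested feature subsets from a VIP ranking
#'
#' Subset `i` contains the `i` top-ranked features, for `i = 1 .. m` where `m`
#' is the total feature count (32 subsets for the full fingerprint).
#'
#' @param ranking A [vip_scores()] result.
#' @return Named list of character vectors (`subset_1` ... `subset_m`).
#' @export
nested_subsets <- function(ranking) {
  stopifnot(inherits(ranking, "vip_ranking"), nrow(ranking) >= 1L)
  feats <- ranking$feature
  out <- lapply(seq_along(feats), function(i) feats[seq_len(i)])
  names(out) <- paste0("subset_", seq_along(feats))
  out
}

#' Kennard-Stone train/test partitioning
#'
#' Deterministic max-min selection in the Euclidean metric on the feature
#' space: the pair of samples at the largest mutual distance seeds the
#' training set; each further training sample is the candidate whose minimum
#' distance to the already selected set is largest. Distance ties break toward
#' the lowest sample index.
#'
#' @param table Feature table data frame or numeric matrix.
#' @param n_train Number of training samples (2 <= n_train <= n).
#'
#' @return An object of class `split_indices`: list with integer `train` and
#'   `test` row indices and, when available, the corresponding `train_ids` /
#'   `test_ids`.
#' @export
kennard_stone <- function(table, n_train) {
  x <- feature_matrix(table)
  n <- nrow(x)
  n_train <- as.integer(n_train)
  if (is.na(n_train) || n_train < 2L || n_train > n) {
    stop("'n_train' must be between 2 and ", n, call. = FALSE)
  }
  d <- as.matrix(stats::dist(x))
  # seed pair: largest distance, ties toward the lowest (i, j)
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] > best_d) {
        best_d <- d[i, j]
        best <- c(i, j)
      }
    }
  }
  selected <- best
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < n_train) {
    min_d <- apply(d[remaining, selected, drop = FALSE], 1L, min)
    pick <- remaining[which.max(min_d)]  # which.max -> lowest index on ties
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  ids <- if (is.data.frame(table) && "sample_id" %in% names(table)) {
    table$sample_id
  } else {
    rownames(x)
  }
  structure(
    list(train = selected, test = remaining,
         train_ids = if (!is.null(ids)) ids[selected],
         test_ids = if (!is.null(ids)) ids[remaining]),
    class = "split_indices"
  )
}

#' @export
print.split_indices <- function(x, ...) {
  cat("Kennard-Stone split:", length(x$train), "training /",
      length(x$test), "testing samples\n")
  invisible(x)
}
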