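# Shared fixtures and independent oracles for the test suite.

# A short array spec: full 16-channel layout, 256 timepoints (enough for a
# depth-3 packet transform, cheap to simulate).
small_spec <- function(n = 256L) sensor_array_spec(n_timepoints = n)

# Small labeled dataset: n_classes x n_reps recordings on the short spec.
small_dataset <- function(n_classes = 3L, n_reps = 4L, seed = 1L, n = 256L,
                          ...) {
  spec <- small_spec(n)
  generate_dataset(make_class_profiles(n_classes, spec), n_reps, spec,
                   seed = seed, ...)
}

small_feature_table <- function(n_classes = 3L, n_reps = 4L, seed = 1L,
                                n = 256L) {
  recs <- small_dataset(n_classes, n_reps, seed, n)
  extract_features(lapply(recs, relative_difference))
}

# Independent greedy Kennard-Stone oracle: plain double loops, no shared code
# with the implementation beyond base R.
ks_oracle <- function(x, n_train) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  best <- c(1L, 2L)
  best_d <- -Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > best_d) {
        best_d <- d[i, j]
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < n_train) {
    rem <- setdiff(seq_len(n), sel)
    mind <- vapply(rem, function(r) min(d[r, sel]), numeric(1))
    sel <- c(sel, rem[which.max(mind)])
  }
  sel
}

# Independent 1-nearest-neighbour oracle (ties to the lowest training index).
nn_oracle <- function(train_x, train_y, test_x) {
  apply(test_x, 1L, function(q) {
    d <- colSums((t(train_x) - q)^2)
    train_y[which.min(d)]
  })
}

# Direct evaluation of Wold's VIP formula from the fitted pieces; independent
# arithmetic from vip_scores().
vip_oracle <- function(model) {
  p <- nrow(model$W)
  sapply(seq_len(p), function(j) {
    num <- sum(model$ssy * (model$W[j, ]^2 / colSums(model$W^2)))
    sqrt(p * num / sum(model$ssy))
  })
}
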