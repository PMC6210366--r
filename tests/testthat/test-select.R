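test_that("PCA explained-variance ratios behave as expected", {
  # exactly rank-2 data: third and later ratios are zero, k = 2 at any cutoff
  set.seed(10)
  base <- matrix(rnorm(40), 20, 2)
  x <- cbind(base, base %*% matrix(c(1, 2, -1, 0.5), 2, 2))
  colnames(x) <- paste0("f", 1:4)
  m <- pca_fit(x)
  expect_lt(sum(m$explained[3:4]), 1e-10)
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_equal(sum(m$explained), 100)
  red <- pca_reduce(m, x, cumulative = 99.99)
  expect_equal(ncol(red), 2L)

  # isotropic 4-feature Gaussian: each ratio near 25%
  set.seed(11)
  iso <- matrix(rnorm(4000 * 4), ncol = 4,
                dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(pca_fit(iso)$explained, rep(25, 4), tolerance = 0.1)
})

test_that("retaining all components reconstructs the centered data", {
  set.seed(12)
  x <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(NULL, paste0("f", 1:6)))
  m <- pca_fit(x)
  scores <- as.matrix(pca_reduce(m, x, k = 6))
  recon <- scores %*% t(m$loadings)
  expect_equal(recon, sweep(x, 2, m$center), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_error(pca_reduce(m, x, k = 7), "between 1 and")
  expect_error(pca_fit(x[1, , drop = FALSE]), "2 samples")
  # loadings orthonormal
  expect_equal(crossprod(m$loadings), diag(6), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("PLS2-NIPALS extracts sensible factors", {
  # Y perfectly predicted by one X column: that column dominates w_1
  set.seed(13)
  x <- cbind(f1 = rep(c(-1, 1), each = 3),
             f2 = rnorm(6, sd = 0.05), f3 = rnorm(6, sd = 0.05))
  labels <- rep(c("a", "b"), each = 3)
  m <- pls2_fit(x, labels, A = 2)
  expect_equal(which.max(abs(m$W[, 1])), c(f1 = 1L))
  expect_gt(abs(m$W[1, 1]), 0.99)
  # unit-norm weights, orthogonal scores
  expect_equal(colSums(m$W^2), rep(1, 2), tolerance = 1e-10)
  expect_lt(abs(crossprod(m$T[, 1], m$T[, 2])), 1e-8)

  expect_error(pls2_fit(x, labels, A = 0), ">= 1")
  expect_error(pls2_fit(x, labels, A = 6), "min\\(n - 1, p\\)")
  expect_error(pls2_fit(x, rep("a", 6)), "2 classes")

  # duplicating every sample leaves the fitted weights unchanged
  m2 <- pls2_fit(rbind(x, x), rep(labels, 2), A = 2)
  expect_equal(abs(m2$W), abs(m$W), tolerance = 1e-6)
})

test_that("VIP scores satisfy Wold's formula and its identity", {
  # hand evaluation: one component, two features, weights (1, 0)
  toy <- structure(list(W = matrix(c(1, 0), 2, 1), ssy = 1, A = 1L,
                        feature_names = c("f1", "f2")),
                   class = "pls2_model")
  v <- vip_scores(toy)
  expect_equal(v$score, c(sqrt(2), 0))
  expect_equal(v$feature, c("f1", "f2"))

  # all features contributing identically -> all scores 1
  even <- structure(list(W = matrix(1 / 2, 4, 1), ssy = 2, A = 1L,
                         feature_names = paste0("f", 1:4)),
                    class = "pls2_model")
  expect_equal(vip_scores(even)$score, rep(1, 4))

  # direct-formula oracle on a small fitted model + mean-square identity
  set.seed(14)
  x <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, c("u", "v", "w")))
  m <- pls2_fit(x, rep(c("a", "b"), 3), A = 2)
  v2 <- vip_scores(m)
  oracle <- vip_oracle(m)
  expect_equal(sort(v2$score), sort(oracle), tolerance = 1e-10)
  expect_equal(mean(v2$score^2), 1, tolerance = 1e-10)
  expect_equal(sum(v2$score^2), 3, tolerance = 1e-10)

  degen <- structure(list(W = matrix(1, 1, 1), ssy = 0, A = 1L,
                          feature_names = "f"), class = "pls2_model")
  expect_error(vip_scores(degen), "degenerate")
})

test_that("VIP ranking is descending with ties broken by feature order", {
  tied <- structure(
    list(W = matrix(c(0, 1 / sqrt(2), 1 / sqrt(2)), 3, 1), ssy = 1, A = 1L,
         feature_names = c("zz", "bb", "aa")),
    class = "pls2_model")
  v <- vip_scores(tied)
  # bb and aa tie on score; bb comes first because it is earlier in the table
  expect_equal(v$feature, c("bb", "aa", "zz"))
  expect_equal(v$rank, 1:3)
  expect_false(v$above_one[3])
})

test_that("nested subsets grow one top-ranked feature at a time", {
  tab <- small_feature_table(3, 4, seed = 15)
  scaled <- apply_scaler(fit_scaler(tab), tab)
  v <- vip_scores(pls2_fit(scaled, A = 2))
  subs <- nested_subsets(v)
  expect_length(subs, 32L)
  expect_equal(subs[[1]], v$feature[1])
  expect_equal(subs[[32]], v$feature)
  for (i in 2:32) {
    expect_equal(setdiff(subs[[i]], subs[[i - 1]]), v$feature[i])
  }
})
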