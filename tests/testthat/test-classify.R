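toy_table <- function(x, labels) {
  data.frame(sample_id = sprintf("s%02d", seq_len(nrow(x))), label = labels,
             x, check.names = FALSE)
}

test_that("PNN recalls stored patterns and breaks ties to the lowest class", {
  x <- matrix(c(0, 0, 1, 1, 0, 1), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("f1", "f2")))
  tab <- toy_table(x, c(1, 2, 3))
  m <- pnn_fit(tab, sigma = 0.05)
  expect_equal(pnn_predict(m, tab), c(1, 2, 3))
  # two equidistant single-pattern classes -> lowest class id
  q <- data.frame(sample_id = "q", label = NA, f1 = 0.5, f2 = 0.5)
  m2 <- pnn_fit(toy_table(x[1:2, ], c(4, 9)), sigma = 0.3)
  expect_equal(pnn_predict(m2, q), 4)
  expect_error(pnn_fit(tab, sigma = 0), "> 0")
  expect_error(pnn_predict(m, data.frame(sample_id = "q", label = 1, g = 1)),
               "missing")
})

test_that("PNN at vanishing spread reproduces a 1-NN oracle", {
  set.seed(19)
  for (rep in 1:50) {
    n_tr <- sample(6:12, 1)
    p <- sample(2:5, 1)
    train_x <- matrix(runif(n_tr * p), n_tr, p,
                      dimnames = list(NULL, paste0("f", 1:p)))
    train_y <- sample(1:4, n_tr, replace = TRUE)
    test_x <- matrix(runif(5 * p), 5, p,
                     dimnames = list(NULL, paste0("f", 1:p)))
    m <- pnn_fit(toy_table(train_x, train_y), sigma = 1e-4)
    pred <- pnn_predict(m, toy_table(test_x, rep(NA, 5)))
    expect_equal(pred, unname(nn_oracle(train_x, train_y, test_x)))
  }
})

test_that("PNN training accuracy reaches 100% as sigma shrinks", {
  set.seed(20)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  tab <- toy_table(x, sample(1:3, 30, replace = TRUE))
  m <- pnn_fit(tab, sigma = 1e-3)
  expect_equal(accuracy(pnn_predict(m, tab), tab$label), 100)
})

test_that("random forest separates distant clusters and is seeded", {
  set.seed(21)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  colnames(x) <- c("f1", "f2")
  tab <- toy_table(x, rep(1:2, each = 20))
  train <- tab[c(1:12, 21:32), ]
  test <- tab[c(13:20, 33:40), ]
  fit <- rf_fit(train, rf_config(n_trees = 25, seed = 77))
  expect_equal(accuracy(rf_predict(fit, test), test$label), 100)
  # determinism: same seed and data -> identical predictions and vote tallies
  fit2 <- rf_fit(train, rf_config(n_trees = 25, seed = 77))
  expect_identical(rf_predict(fit2, test), rf_predict(fit, test))
  expect_identical(fit2$forest$votes, fit$forest$votes)
  expect_equal(fit$mtry, default_mtry(2))
})

test_that("degenerate single-class training data yields a constant predictor", {
  tab <- toy_table(matrix(rnorm(8), 4, 2,
                          dimnames = list(NULL, c("f1", "f2"))), rep(5, 4))
  expect_warning(fit <- rf_fit(tab, rf_config(n_trees = 3)), "single-class")
  expect_equal(rf_predict(fit, tab), rep(5, 4))
})

test_that("accuracy is percent agreement with domain checks", {
  expect_equal(accuracy(1:5, 1:5), 100)
  expect_equal(accuracy(1:4, 5:8), 0)
  expect_equal(accuracy(c(rep(1, 37), 2, 2, 2), rep(1, 40)), 92.5)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("subset evaluation restricts features and finds the arg-max", {
  tab <- small_feature_table(3, 4, seed = 22)
  scaled <- apply_scaler(fit_scaler(tab), tab)
  split <- kennard_stone(scaled, 6)
  feats <- feature_columns(scaled)
  subs <- list(s1 = feats[1:2], s2 = feats[1:16], s3 = feats)
  ev <- evaluate_subsets(scaled, subs, split, n_repeats = 2, seed = 30)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$n_features, c(2L, 16L, 32L))
  expect_true(all(ev$rf_acc >= 0 & ev$rf_acc <= 100))
  expect_true(all(ev$pnn_acc >= 0 & ev$pnn_acc <= 100))
  expect_error(evaluate_subsets(scaled, list(c("AV_T1", "nope")), split),
               "unknown feature")
})

test_that("the identity subset reproduces the direct classifier run", {
  tab <- small_feature_table(2, 4, seed = 23)
  scaled <- apply_scaler(fit_scaler(tab), tab)
  split <- kennard_stone(scaled, 4)
  feats <- feature_columns(scaled)
  ev <- evaluate_subsets(scaled, list(full = feats), split,
                         n_repeats = 2, n_trees = 15, sigma = 0.2, seed = 91)
  train <- scaled[split$train, ]
  test <- scaled[split$test, ]
  seeds <- odorprint:::derive_seeds(91, 2)
  rf_direct <- mean(vapply(seeds, function(s) {
    accuracy(rf_predict(rf_fit(train, rf_config(15, seed = s)), test),
             test$label)
  }, numeric(1)))
  pnn_direct <- accuracy(pnn_predict(pnn_fit(train, sigma = 0.2), test),
                         test$label)
  expect_identical(ev$rf_acc, rf_direct)
  expect_identical(ev$pnn_acc, pnn_direct)
})

test_that("tree sweep covers the grid and reports a stabilization point", {
  tab <- small_feature_table(2, 5, seed = 24)
  scaled <- apply_scaler(fit_scaler(tab), tab)
  split <- kennard_stone(scaled, 5)
  sw <- tree_sweep(scaled, split, n_repeats = 1, seed = 40)
  expect_equal(nrow(sw), 50L)                      # 2..100 step 2
  expect_equal(sw$n_trees, seq(2L, 100L, 2L))
  expect_true(all(sw$train_acc >= 0 & sw$train_acc <= 100))
  stable <- attr(sw, "stable_from")
  expect_true(stable %in% sw$n_trees)
  final <- sw$test_acc[50]
  expect_true(all(abs(sw$test_acc[sw$n_trees >= stable] - final) <= 5))
  # reproducible under a fixed seed
  sw2 <- tree_sweep(scaled, split, n_repeats = 1, seed = 40)
  expect_identical(sw$test_acc, sw2$test_acc)
})
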