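test_that("average value is the arithmetic mean and is linear", {
  expect_equal(average_value(c(1, 2, 3)), 2)
  expect_equal(average_value(rep(0.37, 5940)), 0.37)
  expect_equal(average_value(rep(c(2, -2), 50)), 0)
  expect_error(average_value(numeric(0)), "empty")
  set.seed(3)
  x <- rnorm(100)
  expect_equal(average_value(2.5 * x + 1), 2.5 * average_value(x) + 1)
})

test_that("mean variance averages exactly 2^depth leaf variances", {
  expect_equal(mean_variance(rep(1, 8)), 1)
  expect_equal(mean_variance(c(rep(0, 7), 8)), 1)
  expect_equal(mean_variance(rep(2, 4), depth = 2), 2)
  expect_error(mean_variance(rep(1, 7)), "expected 8")
  # chains the constant-signal case: zero variances average to zero
  expect_equal(mean_variance(wavelet_packet_leaf_variances(rep(5, 64))), 0)
})

test_that("feature extraction yields the named 32-column fingerprint", {
  recs <- lapply(small_dataset(2, 2, seed = 4), relative_difference)
  tab <- extract_features(recs)
  expect_equal(dim(tab), c(4L, 34L))
  expect_equal(names(tab), c("sample_id", "label",
                             fingerprint_feature_names()))
  expect_false(anyNA(tab))
  expect_equal(tab$label, c(1L, 1L, 2L, 2L))
  # deterministic, and permuting recordings permutes rows identically
  perm <- c(3L, 1L, 4L, 2L)
  tab_perm <- extract_features(recs[perm])
  expect_equal(tab_perm, tab[perm, ], ignore_attr = TRUE)
  expect_equal(extract_features(recs), tab)
})

test_that("an all-zero relative recording maps to a zero fingerprint row", {
  spec <- small_spec()
  rec <- structure(
    list(spec = spec, values = matrix(0, 16, 256),
         baseline = stats::setNames(rep(1, 16), spec$channel_names),
         label = 1L, replicate = 1L),
    class = c("relative_recording", "sensor_recording"))
  tab <- extract_features(list(rec))
  expect_equal(unname(unlist(tab[1, -(1:2)])), rep(0, 32))
})

test_that("inconsistent array specs and empty inputs are rejected", {
  recs <- small_dataset(1, 2, seed = 6)
  other <- generate_dataset(
    make_class_profiles(1, small_spec(), informative_channels = "T1"),
    1, sensor_array_spec(c(paste0("T", c(9, 2:8)), paste0("M", 1:8)),
                         n_timepoints = 256),
    seed = 1)
  expect_error(extract_features(c(recs, other)), "different array spec")
  expect_error(extract_features(list()), "no recordings")
})

test_that("leaf variance intermediates export one row per sample-channel", {
  recs <- lapply(small_dataset(2, 1, seed = 8), relative_difference)
  lv <- leaf_variance_table(recs)
  expect_equal(nrow(lv), 2L * 16L)
  expect_equal(names(lv), c("sample_id", "label", "channel", paste0("S", 1:8)))
  # MV features equal the row means of the exported intermediates
  tab <- extract_features(recs)
  mv_t1 <- rowMeans(lv[lv$channel == "T1", paste0("S", 1:8)])
  expect_equal(unname(mv_t1), tab$MV_T1)
})
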