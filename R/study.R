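#' Seeded feature-recovery simulation study
#'
#' Repeats the core analysis on independently simulated datasets and measures
#' how well VIP ranking recovers the informative channels: for each replicate,
#' a dataset with `q` informative channels is simulated, AV/MV features are
#' extracted and normalized, a PLS-DA VIP ranking is computed, and the study
#' records (a) whether the `2q` features of the informative channels occupy
#' the top `2q` VIP ranks and (b) the test accuracies of the full fingerprint
#' versus the best VIP-ranked nested subset for both classifiers.
#'
#' @param n_seeds Number of independent replicates (default 20).
#' @param seed Master seed; replicate seeds derive from it.
#' @param n_classes,n_replicates Simulated design (default 8 x 10).
#' @param n_timepoints Samples per channel (default 5940).
#' @param informative_channels Informative channel set (default the 5-channel
#'   default of [make_class_profiles()]).
#' @param n_repeats RF repetitions averaged per evaluation (default 10).
#' @param n_trees Forest size (default 100).
#' @param sigma PNN spread (default 0.1).
#' @param evaluate_accuracy Also run the (costlier) nested-subset accuracy
#'   comparison (default `TRUE`).
#'
#' @return Data frame with one row per replicate: `seed_index`, `recovered`
#'   (logical), and when `evaluate_accuracy` is set `rf_full`, `rf_best_vip`,
#'   `pnn_full`, `pnn_best_vip`, `best_rf_subset`, `best_pnn_subset`.
#' @export
feature_recovery_study <- function(n_seeds = 20L, seed = 1L,
                                   n_classes = 8L, n_replicates = 10L,
                                   n_timepoints = 5940L,
                                   informative_channels = c("T2", "T5", "M1", "M4", "M7"),
                                   n_repeats = 10L, n_trees = 100L,
                                   sigma = 0.1,
                                   evaluate_accuracy = TRUE) {
  rep_seeds <- derive_seeds(seed, 2L * n_seeds)
  spec <- sensor_array_spec(n_timepoints = n_timepoints)
  profiles <- make_class_profiles(n_classes, spec, informative_channels)
  informative_features <- c(paste0("AV_", informative_channels),
                            paste0("MV_", informative_channels))
  cfg <- wavelet_config()

  rows <- lapply(seq_len(n_seeds), function(i) {
    recs <- generate_dataset(profiles, n_replicates, spec,
                             seed = rep_seeds[i])
    features <- extract_features(lapply(recs, relative_difference), cfg)
    scaled <- apply_scaler(fit_scaler(features), features)
    split <- kennard_stone(scaled, round(nrow(scaled) / 2))
    train <- scaled[split$train, , drop = FALSE]
    A <- min(n_classes - 1L, nrow(train) - 1L)
    vip <- vip_scores(pls2_fit(train, A = A))
    top <- vip$feature[seq_along(informative_features)]
    row <- data.frame(seed_index = i,
                      recovered = setequal(top, informative_features))
    if (evaluate_accuracy) {
      subsets <- nested_subsets(vip)
      ev <- evaluate_subsets(scaled, subsets, split, n_repeats = n_repeats,
                             n_trees = n_trees, sigma = sigma,
                             seed = rep_seeds[n_seeds + i])
      row$rf_full <- ev$rf_acc[nrow(ev)]
      row$pnn_full <- ev$pnn_acc[nrow(ev)]
      row$best_rf_subset <- attr(ev, "best_rf")
      row$best_pnn_subset <- attr(ev, "best_pnn")
      row$rf_best_vip <- ev$rf_acc[row$best_rf_subset]
      row$pnn_best_vip <- ev$pnn_acc[row$best_pnn_subset]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
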