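#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults reproducing
#' the study protocol: 8 classes x 10 replicates of 16 x 5940 recordings, db6
#' depth-3 wavelet packets, (0,1) feature scaling, half Kennard-Stone split,
#' 7-component PLS-DA for VIP, 10 retained principal components, PNN spread
#' 0.1, forests of 100 trees with the `round(sqrt(p))` mtry rule (4 on the
#' 15/16-feature subsets), tree sweep 2..100 step 2 with 100-model averaging.
#'
#' @param seed Master integer seed (required); every stochastic stage derives
#'   its seeds from it.
#' @param out_dir Optional output directory; when set, [run_pipeline()] writes
#'   every artifact as CSV plus a `params.yaml` echo of the configuration.
#' @param n_classes,n_replicates Simulated design (default 8 x 10 = 80).
#' @param n_timepoints Samples per channel (default 5940).
#' @param informative_channels Channels carrying class information in the
#'   simulator (default `T2, T5, M1, M4, M7`).
#' @param drift_slope,noise_sd,baseline_range,response_jitter_sd Simulator
#'   noise model; see [generate_recording()] and [generate_dataset()].
#' @param wavelet A [wavelet_config()].
#' @param split_fraction Training fraction for the Kennard-Stone split
#'   (default 0.5).
#' @param pls_components PLS-DA components for VIP (default `n_classes - 1`).
#' @param pca_components Retained principal components (default 10); set to
#'   `NULL` to use `pca_cumulative` instead.
#' @param pca_cumulative Cumulative explained-variance cutoff in percent, used
#'   when `pca_components` is `NULL`.
#' @param scaler_fit_on `"train"` (default) fits the classification scaler on
#'   the training partition only; `"all"` fits it on the whole table.
#' @param sigma PNN kernel spread (default 0.1).
#' @param n_trees,mtry Forest settings (`mtry = NULL` for the per-subset
#'   square-root rule).
#' @param tree_counts Tree-sweep grid (default `seq(2, 100, 2)`).
#' @param n_repeats Seeded repetitions averaged per stochastic evaluation
#'   (default 100).
#' @param run_tree_sweep Include the tree-count sweep stage (default `TRUE`).
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            out_dir = NULL,
                            n_classes = 8L,
                            n_replicates = 10L,
                            n_timepoints = 5940L,
                            informative_channels = c("T2", "T5", "M1", "M4", "M7"),
                            drift_slope = 2e-6,
                            noise_sd = 0.01,
                            baseline_range = c(1, 3),
                            response_jitter_sd = 0.05,
                            wavelet = wavelet_config(),
                            split_fraction = 0.5,
                            pls_components = n_classes - 1L,
                            pca_components = 10L,
                            pca_cumulative = 99,
                            scaler_fit_on = c("train", "all"),
                            sigma = 0.1,
                            n_trees = 100L,
                            mtry = NULL,
                            tree_counts = seq(2L, 100L, by = 2L),
                            n_repeats = 100L,
                            run_tree_sweep = TRUE) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(inherits(wavelet, "wavelet_config"),
            split_fraction > 0, split_fraction < 1,
            n_classes >= 2, n_replicates >= 1, n_repeats >= 1)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         n_classes = as.integer(n_classes),
         n_replicates = as.integer(n_replicates),
         n_timepoints = as.integer(n_timepoints),
         informative_channels = informative_channels,
         drift_slope = drift_slope, noise_sd = noise_sd,
         baseline_range = baseline_range,
         response_jitter_sd = response_jitter_sd, wavelet = wavelet,
         split_fraction = split_fraction,
         pls_components = as.integer(pls_components),
         pca_components = if (!is.null(pca_components)) as.integer(pca_components),
         pca_cumulative = pca_cumulative,
         scaler_fit_on = match.arg(scaler_fit_on),
         sigma = sigma, n_trees = as.integer(n_trees), mtry = mtry,
         tree_counts = as.integer(tree_counts),
         n_repeats = as.integer(n_repeats),
         run_tree_sweep = isTRUE(run_tree_sweep)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Every key of [pipeline_config()] may appear in the file; `wavelet` is given
#' as a nested map (`family`, `depth`, `boundary_mode`, `leaf_order`,
#' `variance`). Keys absent from the file keep their defaults. `overrides`
#' (e.g. parsed CLI flags) take precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list overriding file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  if (!is.null(vals$wavelet) && !inherits(vals$wavelet, "wavelet_config")) {
    vals$wavelet <- do.call(wavelet_config, vals$wavelet)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

# mean RF accuracy over seeded repeats + PNN accuracy for one feature set
evaluate_cell <- function(train, test, n_repeats, n_trees, mtry, sigma, seed) {
  seeds <- derive_seeds(seed, n_repeats)
  rf_accs <- vapply(seeds, function(s) {
    accuracy(rf_predict(rf_fit(train, rf_config(n_trees, mtry, s)), test),
             test$label)
  }, numeric(1))
  pnn <- pnn_fit(train, sigma = sigma)
  c(rf = mean(rf_accs), pnn = accuracy(pnn_predict(pnn, test), test$label))
}

#' Run the full odor-fingerprint pipeline
#'
#' Executes simulate -> relative difference -> AV/MV feature extraction ->
#' (0,1) scaling -> Kennard-Stone split -> PCA reduction and PLS-DA VIP
#' ranking with nested subsets -> RF and PNN evaluation, and summarizes the
#' six-cell comparison (raw / PCA / VIP x RF / PNN). Reruns with the same
#' configuration are bit-identical, including every written CSV.
#'
#' @param config A [pipeline_config()].
#' @return List with `features` (raw table), `features_scaled`, `split`,
#'   `pca` (model + retained k), `vip` (ranking), `subsets`,
#'   `subset_evaluation`, `tree_sweep` (or `NULL`), and `summary` (six-row
#'   method/accuracy data frame).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_seeds <- derive_seeds(config$seed, 6L)

  # -- simulate -------------------------------------------------------------
  spec <- sensor_array_spec(n_timepoints = config$n_timepoints)
  profiles <- make_class_profiles(config$n_classes, spec,
                                  config$informative_channels)
  recordings <- generate_dataset(profiles, config$n_replicates, spec,
                                 drift_slope = config$drift_slope,
                                 noise_sd = config$noise_sd,
                                 baseline_range = config$baseline_range,
                                 response_jitter_sd = config$response_jitter_sd,
                                 seed = stage_seeds[1L])

  # -- preprocess + features ------------------------------------------------
  rel <- lapply(recordings, relative_difference)
  features <- extract_features(rel, config$wavelet)

  # -- split on the whole-table-normalized feature space --------------------
  scaled_all <- apply_scaler(fit_scaler(features), features)
  n_train <- round(nrow(features) * config$split_fraction)
  split <- kennard_stone(scaled_all, n_train)

  # -- classification scaler policy -----------------------------------------
  table <- if (config$scaler_fit_on == "train") {
    apply_scaler(fit_scaler(features[split$train, , drop = FALSE]), features)
  } else {
    scaled_all
  }
  train <- table[split$train, , drop = FALSE]
  test <- table[split$test, , drop = FALSE]

  # -- raw (full fingerprint) cell ------------------------------------------
  raw_cell <- evaluate_cell(train, test, config$n_repeats, config$n_trees,
                            config$mtry, config$sigma, stage_seeds[2L])

  # -- PCA cell --------------------------------------------------------------
  pca <- pca_fit(train)
  k_req <- config$pca_components
  if (!is.null(k_req)) k_req <- min(k_req, ncol(pca$loadings))
  pc_train <- pca_reduce(pca, train, k = k_req,
                         cumulative = config$pca_cumulative)
  k_used <- length(feature_columns(pc_train))
  pc_test <- pca_reduce(pca, test, k = k_used)
  pc_scaler <- fit_scaler(pc_train)
  pca_cell <- evaluate_cell(apply_scaler(pc_scaler, pc_train),
                            apply_scaler(pc_scaler, pc_test),
                            config$n_repeats, config$n_trees, config$mtry,
                            config$sigma, stage_seeds[3L])

  # -- VIP ranking + nested-subset sweep ------------------------------------
  A <- min(config$pls_components, nrow(train) - 1L,
           length(feature_columns(train)))
  pls <- pls2_fit(train, A = A)
  vip <- vip_scores(pls)
  subsets <- nested_subsets(vip)
  subset_eval <- evaluate_subsets(table, subsets, split,
                                  n_repeats = config$n_repeats,
                                  n_trees = config$n_trees,
                                  mtry = config$mtry, sigma = config$sigma,
                                  seed = stage_seeds[4L])
  best_rf <- attr(subset_eval, "best_rf")
  best_pnn <- attr(subset_eval, "best_pnn")

  summary <- data.frame(
    method = c("RF", "PNN", "PCA-RF", "PCA-PNN", "VIP-RF", "VIP-PNN"),
    accuracy = c(raw_cell[["rf"]], raw_cell[["pnn"]],
                 pca_cell[["rf"]], pca_cell[["pnn"]],
                 subset_eval$rf_acc[best_rf], subset_eval$pnn_acc[best_pnn]),
    detail = c("32 features", "32 features",
               paste0(k_used, " components"), paste0(k_used, " components"),
               paste0("subset #", best_rf), paste0("subset #", best_pnn))
  )

  # -- tree sweep on the VIP-selected RF subset -----------------------------
  sweep_res <- NULL
  if (config$run_tree_sweep) {
    vip_table <- table[, c("sample_id", "label", subsets[[best_rf]]),
                       drop = FALSE]
    sweep_res <- tree_sweep(vip_table, split, mtry = config$mtry,
                            tree_counts = config$tree_counts,
                            n_repeats = config$n_repeats,
                            seed = stage_seeds[5L])
  }

  result <- list(features = features, features_scaled = table, split = split,
                 pca = list(model = pca, k = k_used), vip = vip,
                 subsets = subsets, subset_evaluation = subset_eval,
                 tree_sweep = sweep_res, summary = summary,
                 config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_feature_table(features, out("features.csv"))
    write_feature_table(table, out("features_normalized.csv"))
    write_split(split, out("split.csv"))
    write_vip(vip, out("vip.csv"))
    utils::write.csv(as.data.frame(subset_eval),
                     out("subset_evaluation.csv"), row.names = FALSE)
    if (!is.null(sweep_res)) {
      utils::write.csv(as.data.frame(sweep_res), out("tree_sweep.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(summary, out("summary.csv"), row.names = FALSE)
    cfg_echo <- config
    cfg_echo$wavelet <- unclass(cfg_echo$wavelet)
    yaml::write_yaml(lapply(unclass(cfg_echo), function(v) v),
                     out("params.yaml"))
  }
  result
}
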