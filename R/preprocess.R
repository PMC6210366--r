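#' Relative-difference drift suppression
#'
#' Transforms a raw recording into dimensionless relative responses
#' `y_s(t) = (x_s(t) - x_s(0)) / x_s(0)`, where `x_s(0)` is the channel's
#' stored pre-injection baseline (zero value). Any multiplicative gain change
#' that scales a channel and its baseline by the same factor leaves the output
#' unchanged, which is what suppresses multiplicative sensor drift.
#'
#' @param rec A `sensor_recording` with strictly positive baselines.
#'
#' @return An object of class `relative_recording` with the same shape as the
#'   input but dimensionless `values`.
#' @export
relative_difference <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  bad <- which(!is.finite(rec$baseline) | rec$baseline <= 0)
  if (length(bad)) {
    stop("non-positive baseline on channel ",
         paste(rec$spec$channel_names[bad], collapse = ", "), call. = FALSE)
  }
  values <- sweep(rec$values, 1L, rec$baseline, "-")
  values <- sweep(values, 1L, rec$baseline, "/")
  structure(
    list(spec = rec$spec, values = values, baseline = rec$baseline,
         label = rec$label, replicate = rec$replicate),
    class = c("relative_recording", "sensor_recording")
  )
}

#' Column names of the feature block of a feature table
#'
#' @param table A feature table data frame (`sample_id`, `label`, features).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "label"))
}

#' Fit a min-max scaler on a feature table
#'
#' Learns per-feature minima and maxima from a reference (normally training)
#' table, mapping each non-degenerate feature onto \[0, 1\]. Features whose
#' minimum equals their maximum are flagged degenerate and later mapped to the
#' midpoint 0.5.
#'
#' @param table A feature table data frame.
#' @return An object of class `scaler_params` with fields `min`, `max`,
#'   `degenerate` (all named by feature).
#' @export
fit_scaler <- function(table) {
  feats <- feature_columns(table)
  if (!nrow(table) || !length(feats)) {
    stop("cannot fit a scaler on an empty table", call. = FALSE)
  }
  x <- as.matrix(table[, feats, drop = FALSE])
  mn <- apply(x, 2L, min)
  mx <- apply(x, 2L, max)
  structure(list(min = mn, max = mx, degenerate = mx == mn),
            class = "scaler_params")
}

#' Apply a fitted min-max scaler
#'
#' Scales each feature by the stored training minimum and maximum; values
#' outside the training range (on new tables) are clipped to \[0, 1\];
#' degenerate features map to 0.5.
#'
#' @param params A [fit_scaler()] result.
#' @param table A feature table whose feature names match the fit.
#' @return The table with features scaled into \[0, 1\].
#' @export
apply_scaler <- function(params, table) {
  stopifnot(inherits(params, "scaler_params"))
  feats <- feature_columns(table)
  if (!setequal(feats, names(params$min))) {
    stop("feature names do not match the fitted scaler", call. = FALSE)
  }
  out <- table
  for (f in feats) {
    if (params$degenerate[[f]]) {
      out[[f]] <- rep(0.5, nrow(table))
    } else {
      v <- (table[[f]] - params$min[[f]]) / (params$max[[f]] - params$min[[f]])
      out[[f]] <- pmin(1, pmax(0, v))
    }
  }
  out
}
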