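#' Time-domain average value of a signal
#'
#' The AV feature: arithmetic mean of a channel's (relative) response over all
#' time points.
#'
#' @param series Non-empty numeric vector.
#' @return Scalar mean.
#' @export
average_value <- function(series) {
  if (!length(series)) stop("empty series", call. = FALSE)
  if (any(!is.finite(series))) stop("series must be finite", call. = FALSE)
  mean(series)
}

#' Frequency-domain mean of wavelet-packet leaf variances
#'
#' The MV feature: arithmetic mean of the `2^depth` leaf coefficient
#' variances of one channel.
#'
#' @param leaf_variances Numeric vector of exactly `2^depth` values.
#' @param depth Decomposition depth the variances came from (default 3).
#' @return Scalar mean.
#' @export
mean_variance <- function(leaf_variances, depth = 3L) {
  if (length(leaf_variances) != 2L^depth) {
    stop("expected ", 2L^depth, " leaf variances, got ",
         length(leaf_variances), call. = FALSE)
  }
  mean(leaf_variances)
}

#' Fingerprint feature names for an array
#'
#' @param channel_names Channel names in array order.
#' @return `AV_<channel>` for every channel followed by `MV_<channel>`.
#' @export
fingerprint_feature_names <- function(channel_names = default_channel_names()) {
  c(paste0("AV_", channel_names), paste0("MV_", channel_names))
}

#' Extract the fused odor-fingerprint feature table
#'
#' For each recording and each channel, computes the time-domain mean (AV) and
#' the mean of the wavelet-packet leaf variances (MV), yielding a
#' `2 * n_channels` fingerprint per sample (32 features for the default
#' 16-channel array). Row order follows the input order; the extraction is
#' fully deterministic.
#'
#' @param recordings List of `relative_recording` (or raw `sensor_recording`)
#'   objects sharing one array spec.
#' @param cfg A [wavelet_config()].
#'
#' @return A feature table data frame with columns `sample_id`, `label`, then
#'   the `AV_*` and `MV_*` features.
#' @export
extract_features <- function(recordings, cfg = wavelet_config()) {
  if (!length(recordings)) stop("no recordings", call. = FALSE)
  ch <- recordings[[1L]]$spec$channel_names
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    if (!identical(rec$spec$channel_names, ch)) {
      stop("recording ", i, " has a different array spec", call. = FALSE)
    }
    av <- apply(rec$values, 1L, average_value)
    mv <- apply(rec$values, 1L, function(x) {
      mean_variance(wavelet_packet_leaf_variances(x, cfg), cfg$depth)
    })
    c(av, mv)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- fingerprint_feature_names(ch)
  out <- data.frame(
    sample_id = vapply(recordings, function(r) {
      sprintf("c%d_r%d", r$label, r$replicate)
    }, character(1)),
    label = vapply(recordings, function(r) as.integer(r$label), integer(1)),
    mat,
    check.names = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-channel wavelet-packet leaf variances for every sample
#'
#' Exports the intermediate leaf variances behind the MV features: one row per
#' sample and channel, one column per leaf.
#'
#' @inheritParams extract_features
#' @return Data frame with `sample_id`, `label`, `channel`, `S1..S<2^depth>`.
#' @export
leaf_variance_table <- function(recordings, cfg = wavelet_config()) {
  if (!length(recordings)) stop("no recordings", call. = FALSE)
  n_leaf <- 2L^cfg$depth
  rows <- do.call(rbind, lapply(recordings, function(rec) {
    v <- t(apply(rec$values, 1L, wavelet_packet_leaf_variances, cfg = cfg))
    data.frame(sample_id = sprintf("c%d_r%d", rec$label, rec$replicate),
               label = rec$label,
               channel = rec$spec$channel_names,
               v, check.names = FALSE)
  }))
  names(rows)[-(1:3)] <- paste0("S", seq_len(n_leaf))
  rownames(rows) <- NULL
  rows
}
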