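#' Write recordings to per-sample CSV files plus a manifest
#'
#' Each recording becomes one CSV (rows = timepoints, columns = the 16 channel
#' names). A `manifest.csv` lists `file`, `label`, `replicate` and the
#' per-channel baselines (`baseline_<channel>`).
#'
#' @param recordings List of `sensor_recording` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_recordings <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ch <- recordings[[1L]]$spec$channel_names
  files <- character(length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    files[i] <- sprintf("recording_%03d_c%d_r%d.csv", i, rec$label,
                        rec$replicate)
    df <- as.data.frame(t(rec$values))
    names(df) <- ch
    utils::write.csv(df, file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- data.frame(
    file = files,
    label = vapply(recordings, function(r) as.integer(r$label), integer(1)),
    replicate = vapply(recordings, function(r) r$replicate, integer(1))
  )
  bl <- t(vapply(recordings, function(r) r$baseline, numeric(length(ch))))
  colnames(bl) <- paste0("baseline_", ch)
  manifest <- cbind(manifest, bl)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read recordings written by [write_recordings()]
#'
#' Validates the manifest and every referenced file: all 16 expected channel
#' columns must be present, values numeric and finite, baselines strictly
#' positive. Violations raise errors naming the file (and channel/row).
#'
#' @param manifest_path Path to `manifest.csv`.
#' @param spec The [sensor_array_spec()] the files must conform to; the
#'   default infers `n_timepoints` from the first file.
#' @return List of `sensor_recording` objects.
#' @export
read_recordings <- function(manifest_path, spec = NULL) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, check.names = FALSE)
  dir <- dirname(manifest_path)
  ch <- if (is.null(spec)) default_channel_names() else spec$channel_names
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) {
      stop("manifest row ", i, " references a missing file: ",
           manifest$file[i], call. = FALSE)
    }
    df <- utils::read.csv(f, check.names = FALSE)
    missing <- setdiff(ch, names(df))
    if (length(missing)) {
      stop(manifest$file[i], ": missing channel column(s) ",
           paste(missing, collapse = ", "), "; expected exactly: ",
           paste(ch, collapse = ", "), call. = FALSE)
    }
    values <- t(as.matrix(df[, ch, drop = FALSE]))
    if (!is.numeric(values) || any(!is.finite(values))) {
      stop(manifest$file[i], ": non-numeric or non-finite values",
           call. = FALSE)
    }
    baseline <- as.numeric(manifest[i, paste0("baseline_", ch)])
    names(baseline) <- ch
    if (any(!is.finite(baseline)) || any(baseline <= 0)) {
      stop("manifest row ", i, ": baseline must be > 0", call. = FALSE)
    }
    this_spec <- if (is.null(spec)) {
      sensor_array_spec(ch, n_timepoints = ncol(values))
    } else {
      spec
    }
    structure(
      list(spec = this_spec, values = values, baseline = baseline,
           label = as.integer(manifest$label[i]),
           replicate = as.integer(manifest$replicate[i])),
      class = "sensor_recording"
    )
  })
}

#' Write / read a feature table CSV
#'
#' Layout: first column `sample_id`, second `label`, then the named feature
#' columns (`AV_T1 .. MV_M8` for the full fingerprint).
#'
#' @param table Feature table data frame.
#' @param path CSV path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("feature table must have 'sample_id' and 'label' columns",
         call. = FALSE)
  }
  df
}

#' Export a Kennard-Stone split as CSV
#'
#' Two columns: `sample_id`, `partition` (`training`/`testing`).
#'
#' @param split A [kennard_stone()] result with sample ids.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_indices"))
  df <- data.frame(
    sample_id = c(split$train_ids, split$test_ids),
    partition = rep(c("training", "testing"),
                    c(length(split$train), length(split$test)))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a VIP ranking as CSV
#'
#' @param ranking A [vip_scores()] result.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_vip <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE)
  invisible(path)
}
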