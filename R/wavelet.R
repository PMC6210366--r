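# Orthonormal Daubechies decomposition filters (standard published values).
wavelet_filters <- function(family) {
  dec_lo <- switch(family,
    haar = ,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db6 = c(-0.0010773010853084796, 0.0047772575109455108,
            0.00055384220116149613, -0.03158203931748603,
            0.027522865530305727, 0.097501605587323043,
            -0.12976686756726194, -0.22626469396543983,
            0.31525035170919763, 0.75113390802109536,
            0.49462389039845306, 0.11154074335010947),
    stop("unsupported wavelet family '", family, "' (available: db1, db6)",
         call. = FALSE)
  )
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^seq_len(L)
  list(lo = dec_lo, hi = dec_hi, length = L)
}

# One periodized analysis step: a_k = sum_m f[m] x[(2k - m + L/2) mod n].
# Odd-length inputs are padded by repeating the last sample. For even n this
# is an orthogonal (energy-preserving) circular transform.
dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  half <- n %/% 2L
  L <- filt$length
  k2 <- 2L * (0:(half - 1L)) + L %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  for (m in 0:(L - 1L)) {
    xi <- x[((k2 - m) %% n) + 1L]
    a <- a + filt$lo[m + 1L] * xi
    d <- d + filt$hi[m + 1L] * xi
  }
  list(a = a, d = d)
}

# Symmetric (half-point reflection) extension variant; not energy preserving.
dwt_step_symmetric <- function(x, filt) {
  n <- length(x)
  L <- filt$length
  pad <- rev(seq_len(min(L, n)))
  x_ext <- c(x[pad], x, x[n + 1L - pad])
  res <- dwt_step(x_ext, filt)
  off <- length(pad) %/% 2L
  half <- ceiling(n / 2)
  list(a = res$a[off + seq_len(half)], d = res$d[off + seq_len(half)])
}

# Natural (filter-bank) -> frequency band ordering permutation of 2^depth
# leaves: children of a node keep (low, high) order at even frequency
# positions and flip at odd positions.
leaf_frequency_order <- function(depth) {
  ord <- 1L
  for (lev in seq_len(depth)) {
    nxt <- integer(2L * length(ord))
    for (i in seq_along(ord)) {
      children <- c(2L * ord[i] - 1L, 2L * ord[i])
      if ((i - 1L) %% 2L == 1L) children <- rev(children)
      nxt[c(2L * i - 1L, 2L * i)] <- children
    }
    ord <- nxt
  }
  ord
}

#' Wavelet packet configuration
#'
#' @param family Wavelet family; `"db6"` (default) or `"db1"`/`"haar"`.
#' @param depth Decomposition depth (default 3, giving `2^3 = 8` leaves).
#' @param boundary_mode `"periodization"` (default; orthogonal, satisfies
#'   Parseval exactly on lengths divisible by `2^depth`) or `"symmetric"`
#'   (reflection extension, for matching toolchains that use it).
#' @param leaf_order `"natural"` (filter-bank, default) or `"frequency"`.
#' @param variance `"population"` (divide by n, default) or `"sample"`.
#'
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(family = "db6", depth = 3L,
                           boundary_mode = c("periodization", "symmetric"),
                           leaf_order = c("natural", "frequency"),
                           variance = c("population", "sample")) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("'depth' must be >= 1", call. = FALSE)
  wavelet_filters(family)  # validates the family
  structure(
    list(family = family, depth = depth,
         boundary_mode = match.arg(boundary_mode),
         leaf_order = match.arg(leaf_order),
         variance = match.arg(variance)),
    class = "wavelet_config"
  )
}

#' Wavelet-packet leaf coefficient sequences
#'
#' Computes the full wavelet packet tree (both approximation and detail bands
#' are split at every level) to the configured depth and returns the
#' `2^depth` leaf coefficient sequences. Under the orthonormal periodization
#' mode the total leaf energy equals the signal energy (Parseval) whenever the
#' signal length is divisible by `2^depth`.
#'
#' @param series Numeric signal of length at least `2^depth`.
#' @param cfg A [wavelet_config()].
#'
#' @return List of `2^depth` numeric vectors, ordered per `cfg$leaf_order`.
#' @export
wavelet_packet_coefficients <- function(series, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  series <- as.numeric(series)
  min_len <- 2L^cfg$depth
  if (length(series) < min_len || any(!is.finite(series))) {
    stop("series must be finite with length >= ", min_len,
         " for depth ", cfg$depth, call. = FALSE)
  }
  filt <- wavelet_filters(cfg$family)
  step <- switch(cfg$boundary_mode,
                 periodization = dwt_step,
                 symmetric = dwt_step_symmetric)
  nodes <- list(series)
  for (lev in seq_len(cfg$depth)) {
    nodes <- unlist(lapply(nodes, function(x) {
      r <- step(x, filt)
      list(r$a, r$d)
    }), recursive = FALSE)
  }
  if (cfg$leaf_order == "frequency") {
    nodes <- nodes[leaf_frequency_order(cfg$depth)]
  }
  nodes
}

#' Wavelet-packet leaf coefficient variances
#'
#' Variance of each leaf sequence of [wavelet_packet_coefficients()]. With the
#' defaults (db6, depth 3) this yields the eight per-channel variances
#' averaged into the frequency-domain MV feature.
#'
#' @inheritParams wavelet_packet_coefficients
#' @return Numeric vector of `2^depth` leaf variances.
#' @export
wavelet_packet_leaf_variances <- function(series, cfg = wavelet_config()) {
  nodes <- wavelet_packet_coefficients(series, cfg)
  if (cfg$variance == "population") {
    vapply(nodes, function(v) mean((v - mean(v))^2), numeric(1))
  } else {
    vapply(nodes, stats::var, numeric(1))
  }
}
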