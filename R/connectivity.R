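#' Zero-phase band-pass filter
#'
#' Forward–backward Butterworth band-pass (order 4 per pass), so the
#' output is zero-phase and the effective attenuation is doubled.
#'
#' @param x numeric vector or channels-by-samples matrix.
#' @param band a row of a band table (`low`, `high` in Hz) or a length-2
#'   numeric.
#' @param sampling_rate Hz.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, band, sampling_rate, order = 4) {
  if (is.data.frame(band) || is.list(band)) band <- c(band$low, band$high)
  nyq <- sampling_rate / 2
  assert_that(band[2] < nyq,
              sprintf("band edge %g Hz is not below Nyquist (%g Hz)",
                      band[2], nyq))
  assert_that(band[1] > 0 && band[1] < band[2], "invalid band edges")
  bf <- signal::butter(order, band / nyq, type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Remove the zero-lag component of one signal from another
#'
#' Time-domain regression: returns `y - (<y,x>/<x,x>) x`, the part of `y`
#' orthogonal to `x`. Because instantaneous leakage (volume conduction /
#' field spread) mixes sources with zero lag, the removed component is
#' exactly the spurious shared part; genuine amplitude coupling carried
#' on phase-shifted oscillations survives.
#'
#' @param y,x equal-length numeric vectors; `x` must not be identically
#'   zero.
#' @return The orthogonalized `y`.
#' @export
orthogonalize <- function(y, x) {
  assert_that(length(y) == length(x), "signals must have equal length")
  xx <- sum(x * x)
  assert_that(xx > 0, "cannot orthogonalize against an all-zero signal")
  y - (sum(y * x) / xx) * x
}

#' Amplitude envelope of a signal
#'
#' The modulus of the analytic signal (frequency-domain Hilbert
#' transform). For a narrowband carrier `a cos(2 pi f t)` the envelope
#' equals `a` away from the segment edges.
#'
#' @param x finite numeric vector.
#' @return Non-negative envelope, same length as `x`.
#' @export
envelope <- function(x) {
  Mod(analytic_signal(x))
}

#' Leakage-corrected amplitude envelope correlation of a signal pair
#'
#' Both signals are band-passed, then the correction is applied in both
#' directions: `r1` correlates the envelope of `x` with the envelope of
#' `y` orthogonalized with respect to `x`, `r2` the reverse, and the
#' AEC-c value is their mean — symmetric by construction. Filter and
#' Hilbert transients are excluded by trimming `trim` seconds from each
#' side before correlating. A degenerate orthogonalized signal
#' (near-zero envelope variance) contributes 0.
#'
#' @param x,y equal-length signals spanning at least 10 cycles of the
#'   band's low edge.
#' @param band band definition row or length-2 numeric (Hz).
#' @param sampling_rate Hz.
#' @param trim seconds discarded at each end before correlation
#'   (default 1).
#' @param rectify take the absolute value of the result (default FALSE:
#'   the raw signed correlation is reported).
#' @return The AEC-c value in \[-1, 1\].
#' @export
aecc_pair <- function(x, y, band, sampling_rate, trim = 1,
                      rectify = FALSE) {
  if (is.data.frame(band) || is.list(band)) band <- c(band$low, band$high)
  assert_that(length(x) == length(y), "signals must have equal length")
  assert_that(length(x) / sampling_rate >= 10 / band[1],
              sprintf("signals must span at least 10 cycles of %g Hz",
                      band[1]))
  xb <- bandpass(x, band, sampling_rate)
  yb <- bandpass(y, band, sampling_rate)
  keep <- trim_index(length(x), sampling_rate, trim)
  ex <- envelope(xb)[keep]
  ey <- envelope(yb)[keep]
  r1 <- env_cor(ex, envelope(orthogonalize(yb, xb))[keep])
  r2 <- env_cor(ey, envelope(orthogonalize(xb, yb))[keep])
  val <- (r1 + r2) / 2
  if (rectify) abs(val) else val
}

trim_index <- function(n, fs, trim) {
  k <- round(trim * fs)
  assert_that(n - 2L * k >= 8L, "signal too short after transient trimming")
  (k + 1L):(n - k)
}

env_cor <- function(a, b) {
  if (stats::sd(b) < 1e-12 || stats::sd(a) < 1e-12) return(0)
  stats::cor(a, b)
}

#' Band-specific AEC-c adjacency matrix with node strengths
#'
#' Computes the full symmetric adjacency over all unordered channel
#' pairs (66 pairs for the 12-ROI network), with zero diagonal. The node
#' strength of a region is the sum of its pairwise AEC-c values with the
#' other regions (11 terms in the 12-ROI network); the relative node
#' strength divides by the band's total node strength, so relative
#' values sum to one.
#'
#' @param x a `recording`/`data_segment` or channels-by-samples matrix.
#' @param band band definition row (or length-2 numeric, Hz).
#' @param sampling_rate required for matrix input.
#' @param n_roi expected channel count (default 12; set to the actual
#'   count for non-DMN networks).
#' @param trim,rectify passed to [aecc_pair()].
#' @return An object of class `connectivity_matrix` with `band`, `aecc`,
#'   `node_strength`, `relative_node_strength` and `labels`.
#' @export
adjacency <- function(x, band, sampling_rate = NULL, n_roi = 12L,
                      trim = 1, rectify = FALSE) {
  if (is.data.frame(band) || is.list(band)) {
    band_name <- band$name %||% paste0(band[1], "-", band[2], "Hz")
    band <- c(band$low, band$high)
  } else {
    band_name <- paste0(band[1], "-", band[2], "Hz")
  }
  if (inherits(x, "recording") || inherits(x, "data_segment")) {
    sampling_rate <- x$sampling_rate
    labels <- rownames(x$data) %||% sprintf("ch%02d", seq_len(nrow(x$data)))
    x <- x$data
  } else {
    x <- as.matrix(x)
    assert_that(!is.null(sampling_rate),
                "sampling_rate required for matrix input")
    labels <- rownames(x) %||% sprintf("ch%02d", seq_len(nrow(x)))
  }
  p <- nrow(x)
  assert_that(p == n_roi,
              sprintf("expected %d channels, found %d", n_roi, p))
  assert_that(ncol(x) / sampling_rate >= 10 / band[1],
              sprintf("segment must span at least 10 cycles of %g Hz",
                      band[1]))
  xb <- t(apply(x, 1L, function(row) bandpass(row, band, sampling_rate)))
  keep <- trim_index(ncol(x), sampling_rate, trim)
  envs <- t(apply(xb, 1L, function(row) envelope(row)))[, keep,
                                                        drop = FALSE]
  a <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      r1 <- env_cor(envs[i, ], envelope(orthogonalize(xb[j, ], xb[i, ]))[keep])
      r2 <- env_cor(envs[j, ], envelope(orthogonalize(xb[i, ], xb[j, ]))[keep])
      v <- (r1 + r2) / 2
      if (rectify) v <- abs(v)
      a[i, j] <- a[j, i] <- v
    }
  }
  new_connectivity_matrix(a, band_name)
}

new_connectivity_matrix <- function(aecc, band_name) {
  assert_that(max(abs(aecc - t(aecc))) == 0, "adjacency must be symmetric")
  assert_that(all(diag(aecc) == 0), "adjacency diagonal must be zero")
  ns <- rowSums(aecc)
  tot <- sum(ns)
  rel <- if (abs(tot) > 0) ns / tot else rep(NA_real_, length(ns))
  structure(list(band = band_name, aecc = aecc, node_strength = ns,
                 relative_node_strength = rel,
                 labels = rownames(aecc)),
            class = "connectivity_matrix")
}

#' Construct a connectivity matrix from a precomputed adjacency
#'
#' Useful for toy matrices and for reading adjacency tables back from
#' disk.
#'
#' @param aecc symmetric numeric matrix with zero diagonal.
#' @param band_name label for the band.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(aecc, band_name = "band") {
  aecc <- as.matrix(aecc)
  if (is.null(rownames(aecc))) {
    rownames(aecc) <- colnames(aecc) <- sprintf("ch%02d",
                                                seq_len(nrow(aecc)))
  }
  new_connectivity_matrix(aecc, band_name)
}

#' Node strength and relative node strength
#'
#' Node strength is the row sum of the adjacency (the sum of a region's
#' pairwise AEC-c values with every other region); relative node
#' strength is the ratio of a node's strength to the band's total node
#' strength, and sums to one when the total is non-zero. A zero total
#' makes the relative values undefined; they are reported as `NA`.
#'
#' @param m a `connectivity_matrix`.
#' @return Named numeric vector.
#' @export
node_strength <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  rowSums(m$aecc)
}

#' @rdname node_strength
#' @export
relative_node_strength <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  ns <- rowSums(m$aecc)
  tot <- sum(ns)
  if (abs(tot) == 0) return(stats::setNames(rep(NA_real_, length(ns)),
                                            names(ns)))
  ns / tot
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> band %s, %d nodes, mean AEC-c %.4f\n",
              x$band, nrow(x$aecc),
              mean(x$aecc[upper.tri(x$aecc)])))
  invisible(x)
}
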