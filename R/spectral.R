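#' Canonical six-band definition
#'
#' delta 2–4, theta 5–7, alpha 8–12, beta 15–29, gamma1 30–59 and gamma2
#' 60–90 Hz. Band edges are inclusive on both sides; bins falling in the
#' inter-band gaps (4–5, 7–8, 12–15, 29–30, 59–60 Hz) belong to no band.
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2"),
             low = c(2, 5, 8, 15, 30, 60),
             high = c(4, 7, 12, 29, 59, 90))
}

validate_bands <- function(bands) {
  assert_that(all(c("name", "low", "high") %in% names(bands)),
              "bands need columns name, low, high")
  assert_that(all(bands$low < bands$high), "band low must be below high")
  assert_that(!anyDuplicated(bands$name), "band names must be unique")
  b <- bands[order(bands$low), , drop = FALSE]
  if (nrow(b) > 1L) {
    assert_that(all(b$low[-1L] > b$high[-nrow(b)]),
                "bands must not overlap")
  }
  bands
}

#' Welch power spectral density of a segment
#'
#' Averaged modified periodograms: the signal is split into
#' Hann-tapered windows of `window_s` seconds with fractional `overlap`,
#' each window is demeaned, and the one-sided periodograms are averaged.
#' Frequency resolution is `1/window_s`. A segment exactly one window
#' long (e.g. a 5 s ictal window with the 5 s default) degenerates to a
#' single periodogram.
#'
#' @param x a `data_segment`, `recording`, or channels-by-samples matrix.
#' @param sampling_rate required when `x` is a bare matrix.
#' @param window_s window duration in seconds (default 5).
#' @param overlap fractional overlap in \[0, 1) (default 0.5).
#' @return An object of class `spectral_result` with `freqs` (Hz), `psd`
#'   (channels x frequency, density units), `channel_labels`, `window_s`
#'   and `overlap`. `rel_psd` is filled by [relative_psd()].
#' @export
welch_psd <- function(x, sampling_rate = NULL, window_s = 5,
                      overlap = 0.5) {
  if (inherits(x, "data_segment") || inherits(x, "recording")) {
    sampling_rate <- x$sampling_rate
    labels <- if (inherits(x, "recording")) x$channel_labels else
      rownames(x$data) %||% sprintf("ch%02d", seq_len(nrow(x$data)))
    x <- x$data
  } else {
    x <- as.matrix(x)
    assert_that(!is.null(sampling_rate),
                "sampling_rate required for matrix input")
    labels <- rownames(x) %||% sprintf("ch%02d", seq_len(nrow(x)))
  }
  assert_that(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  fs <- sampling_rate
  nwin <- round(window_s * fs)
  assert_that(ncol(x) >= nwin,
              sprintf("segment (%d samples) shorter than one %g s window",
                      ncol(x), window_s))
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, ncol(x) - nwin + 1L, by = step)
  w <- signal::hanning(nwin)
  u <- sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  scale <- 2 / (fs * u)
  psd <- matrix(0, nrow = nrow(x), ncol = nfreq)
  for (ch in seq_len(nrow(x))) {
    acc <- numeric(nfreq)
    for (s0 in starts) {
      seg <- x[ch, s0:(s0 + nwin - 1L)]
      seg <- (seg - mean(seg)) * w
      p <- Mod(stats::fft(seg)[1:nfreq])^2 * scale
      p[1L] <- p[1L] / 2                       # DC not doubled
      if (nwin %% 2L == 0L) p[nfreq] <- p[nfreq] / 2  # Nyquist not doubled
      acc <- acc + p
    }
    psd[ch, ] <- acc / length(starts)
  }
  structure(list(freqs = (seq_len(nfreq) - 1L) * fs / nwin, psd = psd,
                 rel_psd = NULL, rel_freqs = NULL,
                 channel_labels = labels, window_s = window_s,
                 overlap = overlap),
            class = "spectral_result")
}

#' Relative power spectral density
#'
#' Rescales each channel's PSD bin by the channel's total power over the
#' normalization range, so each row of the relative spectrum sums to one:
#' `rel(f) = psd(f) / sum_i psd(f_i)` with `f_i` running over bins in
#' `norm_range`. The default range 1–90 Hz covers the full analysed
#' spectrum while excluding DC/drift bins.
#'
#' @param result a [welch_psd()] result.
#' @param norm_range length-2 numeric, Hz (default `c(1, 90)`).
#' @return The `spectral_result` with `rel_psd` and `rel_freqs` filled.
#' @export
relative_psd <- function(result, norm_range = c(1, 90)) {
  stopifnot(inherits(result, "spectral_result"))
  mask <- result$freqs >= norm_range[1] - 1e-9 &
    result$freqs <= norm_range[2] + 1e-9
  assert_that(sum(mask) > 0L, "no frequency bins inside norm_range")
  sub <- result$psd[, mask, drop = FALSE]
  tot <- rowSums(sub)
  assert_that(all(tot > 0),
              "degenerate (all-zero) spectrum; cannot normalize")
  result$rel_psd <- sub / tot
  result$rel_freqs <- result$freqs[mask]
  result
}

#' Relative band power
#'
#' Sums the relative PSD over the bins of each band, with band edges
#' inclusive on both sides; bins in inter-band gaps contribute to no
#' band, so per-channel band powers sum to at most one.
#'
#' @param result a `spectral_result` with `rel_psd` filled.
#' @param bands band definition table (default [canonical_bands()]).
#' @return Data frame with columns `roi`, `band`, `power`.
#' @export
band_power <- function(result, bands = canonical_bands()) {
  stopifnot(inherits(result, "spectral_result"))
  assert_that(!is.null(result$rel_psd),
              "call relative_psd() before band_power()")
  bands <- validate_bands(bands)
  f <- result$rel_freqs
  for (i in seq_len(nrow(bands))) {
    assert_that(bands$low[i] >= min(f) - 1e-9 &&
                  bands$high[i] <= max(f) + 1e-9,
                sprintf("band %s [%g, %g] lies outside the frequency grid",
                        bands$name[i], bands$low[i], bands$high[i]))
  }
  out <- expand.grid(roi = result$channel_labels, band = bands$name,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$power <- NA_real_
  for (i in seq_len(nrow(bands))) {
    idx <- f >= bands$low[i] - 1e-9 & f <= bands$high[i] + 1e-9
    p <- rowSums(result$rel_psd[, idx, drop = FALSE])
    out$power[out$band == bands$name[i]] <- p
  }
  out
}

#' Detect an alpha-band power peak
#'
#' Looks for a local maximum of the relative PSD inside the alpha range
#' that (a) exceeds `prominence` times the median relative PSD over the
#' surrounding 5–15 Hz neighbourhood and (b) is the maximum over that
#' whole neighbourhood — i.e. the spectrum genuinely peaks in the alpha
#' range rather than merely wiggling there. Resting-state recordings
#' with an intact posterior alpha rhythm show such a peak; during a
#' spike-wave discharge (delta-dominated, harmonic-rich) it is lost.
#'
#' @param result a `spectral_result` with `rel_psd` filled.
#' @param roi channel label or index.
#' @param range alpha search range, Hz (default `c(8, 12)`).
#' @param neighborhood reference range for the prominence test
#'   (default `c(5, 15)`).
#' @param prominence required ratio of peak to neighbourhood median
#'   (default 2).
#' @return The peak frequency in Hz, or `NA_real_` when no qualifying
#'   peak exists.
#' @export
alpha_peak <- function(result, roi = 1L, range = c(8, 12),
                       neighborhood = c(5, 15), prominence = 2) {
  stopifnot(inherits(result, "spectral_result"))
  assert_that(!is.null(result$rel_psd),
              "call relative_psd() before alpha_peak()")
  if (is.character(roi)) roi <- match(roi, result$channel_labels)
  assert_that(!is.na(roi) && roi >= 1L && roi <= nrow(result$rel_psd),
              "unknown roi")
  f <- result$rel_freqs
  y <- result$rel_psd[roi, ]
  in_range <- which(f >= range[1] - 1e-9 & f <= range[2] + 1e-9)
  in_nb <- f >= neighborhood[1] - 1e-9 & f <= neighborhood[2] + 1e-9
  ref <- stats::median(y[in_nb])
  best <- NA_real_; best_val <- -Inf
  for (i in in_range) {
    if (i <= 1L || i >= length(y)) next
    if (y[i] >= y[i - 1L] && y[i] >= y[i + 1L] && y[i] > best_val) {
      best_val <- y[i]; best <- f[i]
    }
  }
  if (is.na(best) || !(best_val > prominence * ref)) return(NA_real_)
  if (best_val < max(y[in_nb])) return(NA_real_)
  best
}
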