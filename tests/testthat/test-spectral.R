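test_that("a pure tone concentrates its Welch spectrum at the tone bin", {
  fs <- 300
  t <- (0:(30 * fs - 1)) / fs
  sp <- welch_psd(matrix(sin(2 * pi * 10 * t), 1), fs)
  peak <- sp$psd[1, which.min(abs(sp$freqs - 10))]
  away <- sp$psd[1, abs(sp$freqs - 10) >= 2]
  expect_true(all(peak > 100 * away))
})

test_that("white noise gives an approximately flat spectrum", {
  set.seed(8)
  fs <- 300
  sp <- welch_psd(matrix(rnorm(30 * fs), 1), fs)
  keep <- sp$freqs >= 2 & sp$freqs <= 140
  smoothed <- stats::filter(sp$psd[1, keep], rep(1 / 11, 11))
  smoothed <- smoothed[!is.na(smoothed)]
  expect_lt(max(smoothed) / min(smoothed), 3)
})

test_that("a one-window segment degenerates to the periodogram", {
  fs <- 300
  set.seed(3)
  x <- matrix(rnorm(5 * fs), 1)
  sp <- welch_psd(x, fs, window_s = 5, overlap = 0.5)
  # brute-force single Hann periodogram with matching scaling
  w <- signal::hanning(5 * fs)
  seg <- (x[1, ] - mean(x[1, ])) * w
  p <- Mod(stats::fft(seg)[1:(5 * fs / 2 + 1)])^2 * 2 / (fs * sum(w^2))
  p[1] <- p[1] / 2; p[length(p)] <- p[length(p)] / 2
  expect_equal(sp$psd[1, ], p, tolerance = 1e-12)
})

test_that("Welch equals the mean of no-overlap window periodograms", {
  fs <- 100
  set.seed(4)
  x <- matrix(rnorm(15 * fs), 1)
  sp <- welch_psd(x, fs, window_s = 5, overlap = 0)
  w <- signal::hanning(5 * fs)
  oracle <- rowMeans(vapply(0:2, function(k) {
    seg <- x[1, (k * 5 * fs + 1):((k + 1) * 5 * fs)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[1:(5 * fs / 2 + 1)])^2 * 2 / (fs * sum(w^2))
    p[1] <- p[1] / 2; p[length(p)] <- p[length(p)] / 2
    p
  }, numeric(5 * fs / 2 + 1)))
  expect_equal(sp$psd[1, ], oracle, tolerance = 1e-12)
})

test_that("integrated PSD approximates the signal variance", {
  set.seed(10)
  fs <- 300
  x <- rnorm(60 * fs) + sin(2 * pi * 11 * (1:(60 * fs)) / fs)
  sp <- welch_psd(matrix(x, 1), fs)
  total <- sum(sp$psd[1, ]) * (fs / (5 * fs))
  expect_equal(total, var(x), tolerance = 0.05)
})

test_that("relative PSD rows are a unit-sum, scale-invariant normalization", {
  cfg <- small_config()
  rec <- simulate_roi_timeseries(cfg, "control", seed = 2, duration = 30)
  sp <- relative_psd(welch_psd(rec))
  expect_equal(rowSums(sp$rel_psd), rep(1, 12), tolerance = 1e-9,
               ignore_attr = TRUE)
  # doubling the input leaves the relative spectrum unchanged
  sp2 <- relative_psd(welch_psd(rec$data * 2, rec$sampling_rate))
  expect_equal(sp2$rel_psd, sp$rel_psd, tolerance = 1e-12,
               ignore_attr = TRUE)
  # uniform psd -> each value 1/nbins
  su <- welch_psd(matrix(rnorm(3000), 1), 100)
  su$psd[] <- 1
  su <- relative_psd(su, c(1, 45))
  expect_equal(unique(round(su$rel_psd[1, ], 12)),
               round(1 / ncol(su$rel_psd), 12))
  # degenerate all-zero spectrum errors
  sz <- welch_psd(matrix(rnorm(3000), 1), 100)
  sz$psd[] <- 0
  expect_error(relative_psd(sz), "degenerate")
})

test_that("band power honours inclusive edges and gap bins", {
  fs <- 300
  t <- (0:(30 * fs - 1)) / fs
  sp <- relative_psd(welch_psd(matrix(sin(2 * pi * 10 * t), 1), fs))
  bp <- band_power(sp)
  expect_gt(bp$power[bp$band == "alpha"], 0.95)
  expect_true(all(bp$power[bp$band != "alpha"] < 0.02))
  # mass placed on a gap bin (13 Hz) belongs to no band
  sp$rel_psd[] <- 0
  sp$rel_psd[1, which.min(abs(sp$rel_freqs - 13))] <- 1
  bp0 <- band_power(sp)
  expect_true(all(bp0$power == 0))
  # band outside the grid errors
  expect_error(band_power(sp, data.frame(name = "hf", low = 120,
                                         high = 160)), "outside")
})

test_that("white-noise band powers scale with bandwidth", {
  set.seed(12)
  sp <- relative_psd(welch_psd(matrix(rnorm(60 * 300), 1), 300))
  bp <- band_power(sp)
  p <- setNames(bp$power, bp$band)
  # power per bin is flat, so band powers are proportional to bin count
  nb <- vapply(seq_len(6), function(i) {
    b <- canonical_bands()[i, ]
    sum(sp$rel_freqs >= b$low - 1e-9 & sp$rel_freqs <= b$high + 1e-9)
  }, numeric(1))
  per_bin <- p / nb
  expect_true(all(abs(per_bin / mean(per_bin) - 1) < 0.15))
  # bands with clearly wider support carry clearly more power
  expect_true(p[["gamma1"]] > p[["beta"]])
  expect_true(p[["beta"]] > p[["alpha"]])
  expect_true(p[["alpha"]] > p[["delta"]])
})

test_that("alpha peak detection separates regimes and rejects flat spectra", {
  cfg <- small_config()
  recc <- simulate_roi_timeseries(cfg, "control", seed = 7, duration = 60)
  spc <- relative_psd(welch_psd(recc))
  pk <- alpha_peak(spc, "PCu.R")
  expect_false(is.na(pk))
  expect_lt(abs(pk - 10), 0.21)  # within one 0.2 Hz bin of the carrier
  reci <- simulate_roi_timeseries(cfg, "ictal", seed = 8, duration = 400)
  seg <- select_ictal(reci)[[1]]
  spi <- relative_psd(welch_psd(seg))
  expect_true(all(is.na(vapply(1:12, function(r) alpha_peak(spi, r),
                               numeric(1)))))
  flat <- spc
  flat$rel_psd[] <- 1 / ncol(flat$rel_psd)
  expect_true(is.na(alpha_peak(flat, 1)))
})

test_that("segments shorter than one window are refused", {
  expect_error(welch_psd(matrix(rnorm(200), 1), 100, window_s = 5),
               "shorter")
})
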