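test_that("identical config and seed give bit-identical recordings", {
  cfg <- small_config()
  a <- simulate_roi_timeseries(cfg, "interictal", seed = 11, duration = 20)
  b <- simulate_roi_timeseries(cfg, "interictal", seed = 11, duration = 20)
  expect_identical(a$data, b$data)
  ia <- simulate_roi_timeseries(cfg, "ictal", seed = 12, duration = 400)
  ib <- simulate_roi_timeseries(cfg, "ictal", seed = 12, duration = 400)
  expect_identical(ia$data, ib$data)
  expect_identical(ia$annotations, ib$annotations)
})

test_that("SWD waveform has its dominant line at the fundamental", {
  fs <- 300
  w <- simulate_swd(5, 3, fs, n_harmonics = 5)
  n <- length(w)
  p <- Mod(stats::fft(w - mean(w)))[1:(n %/% 2)]^2
  f <- (0:(n %/% 2 - 1)) / 5
  expect_equal(f[which.max(p)], 3)
})

test_that("degenerate SWD cases behave", {
  fs <- 300
  t <- (0:(fs - 1)) / fs
  pure <- simulate_swd(1, 3, fs, n_harmonics = 1)
  expect_equal(as.numeric(pure), cos(2 * pi * 3 * t), tolerance = 1e-12)
  expect_length(attr(simulate_swd(1, 3, fs), "spike_times"), 3L)
  expect_error(simulate_swd(1, 3, 300, n_harmonics = 60), "Nyquist")
})

test_that("sensor mixing is the configured linear combination", {
  cfg <- small_config()
  src <- simulate_roi_timeseries(cfg, "control", seed = 2, duration = 2)
  # identity gain, no noise: output equals input
  fwd_id <- forward_model(diag(12))
  out <- mix_to_sensors(src, fwd_id, noise_sd = 0)
  expect_equal(unname(out$data), unname(src$data))
  # zero gain: all-zero sensors
  z <- mix_to_sensors(src, forward_model(matrix(0, 4, 12)), noise_sd = 0)
  expect_true(all(z$data == 0))
  # explicit 2-source / 4-sensor combination, direct multiply oracle
  g <- matrix(c(1, 0, 0.5, 2, 0, 1, 0.25, -1), nrow = 4, byrow = TRUE)
  two <- recording(src$data[1:2, , drop = FALSE], src$sampling_rate,
                   channel_labels = c("a", "b"))
  mixed <- mix_to_sensors(two, forward_model(g), noise_sd = 0)
  expect_equal(unname(mixed$data), unname(g %*% two$data))
  # dimension mismatch
  expect_error(mix_to_sensors(src, forward_model(matrix(1, 3, 5))),
               "column count")
})

test_that("cohort manifest matches the configured design", {
  man <- cohort_manifest(synthetic_config())
  expect_equal(nrow(man), 59L)
  expect_equal(sum(man$group == "patient"), 33L)
  expect_equal(sum(man$group == "control"), 26L)
  expect_false(anyDuplicated(man$subject_id) > 0)
})

test_that("control-only cohorts carry no SWD annotations", {
  cfg <- synthetic_config(n_patients = 0, n_controls = 2,
                          epoch_length = 60, n_epochs_per_subject = 1,
                          seed = 4)
  coh <- make_cohort(cfg)
  expect_equal(nrow(coh$manifest), 2L)
  expect_true(all(vapply(coh$recordings,
                         function(r) nrow(r$annotations) == 0L,
                         logical(1))))
})

test_that("every synthetic patient yields ictal and interictal segments", {
  cfg <- small_config(n_patients = 3, n_controls = 0, seed = 6)
  coh <- make_cohort(cfg)
  for (rec in coh$recordings) {
    segs <- segment_recording(rec)
    conds <- vapply(segs, function(s) s$condition, character(1))
    expect_gte(sum(conds == "ictal"), 1L)
    expect_gte(sum(conds == "interictal"), 1L)
  }
})

test_that("an insufficient epoch budget is refused with the constraint named", {
  cfg <- synthetic_config(n_patients = 1, n_controls = 0,
                          epoch_length = 60, n_epochs_per_subject = 2)
  expect_error(make_cohort(cfg), "epoch budget too small")
})

test_that("unknown regime and invalid configs error", {
  cfg <- small_config()
  expect_error(simulate_roi_timeseries(cfg, "peri-ictal"))
  expect_error(synthetic_config(sampling_rate = 100), "180")
  expect_error(synthetic_config(swd_fundamental = 7), "delta")
  bad_cp <- data.frame(regime = "control", roi_a = "PCC.R",
                       roi_b = "PCu.R", band = "beta", strength = 1.4,
                       phase = 0)
  expect_error(synthetic_config(coupling_spec = bad_cp), "\\[0, 1\\]")
  expect_error(synthetic_config(leakage_matrix = matrix(2, 2, 2) ),
               "unit diagonal")
})

test_that("relative band power rises monotonically with carrier amplitude", {
  powers <- vapply(c(0.4, 1, 2.5), function(a) {
    amps <- default_band_amplitudes()
    amps["control", ] <- 0
    amps["control", "alpha"] <- a
    cfg <- synthetic_config(band_amplitudes = amps,
                            posterior_alpha_gain = 1,
                            coupling_spec = no_coupling(), seed = 3)
    rec <- simulate_roi_timeseries(cfg, "control", seed = 3,
                                   duration = 30)
    bp <- band_power(relative_psd(welch_psd(rec)))
    mean(bp$power[bp$band == "alpha"])
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("recordings round-trip through the text container", {
  cfg <- small_config()
  rec <- simulate_roi_timeseries(cfg, "ictal", seed = 5, duration = 400)
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$annotations$onset, rec$annotations$onset)
  expect_equal(unname(back$data), unname(rec$data), tolerance = 1e-6)
})
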