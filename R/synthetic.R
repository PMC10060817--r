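#' Configuration for the synthetic DMN cohort generator
#'
#' The generator emulates the three recording regimes of a pediatric
#' absence-epilepsy MEG study at source (ROI) level: `control` and
#' `interictal` background activity with a parieto-occipital alpha peak,
#' and `ictal` recordings in which 3 Hz harmonic-rich spike-wave bursts
#' (SWDs) override the background and suppress the alpha rhythm. Each ROI
#' signal is 1/f-coloured noise plus per-band amplitude-modulated
#' carriers; selected ROI pairs share a slow envelope modulator so that
#' genuine amplitude-envelope coupling exists for the connectivity stage
#' to recover, with carriers offset in phase (default pi/2) so that
#' zero-lag orthogonalization does not remove the coupling. A leakage
#' matrix applies instantaneous linear mixing last, emulating volume
#' conduction / field spread.
#'
#' @param sampling_rate Hz; must be at least twice the highest analysed
#'   band edge (90 Hz). Default 300.
#' @param epoch_length epoch duration in seconds (default 120).
#' @param n_epochs_per_subject consecutive epochs per subject (default 5,
#'   i.e. 10 min of continuous recording).
#' @param n_patients,n_controls cohort sizes (defaults 33 and 26).
#' @param band_amplitudes 3 x 6 matrix (regimes x bands) of carrier
#'   amplitudes; see [default_band_amplitudes()].
#' @param posterior_alpha_gain multiplier on the alpha carrier for
#'   posterior ROIs (PCC, PCu, IPL), producing the parieto-occipital
#'   alpha dominance seen at rest. Default 2.5.
#' @param one_over_f_exponent spectral slope of the background noise.
#' @param noise_sd standard deviation of the 1/f background.
#' @param coupling_spec data frame with columns `regime`, `roi_a`,
#'   `roi_b`, `band`, `strength` (in \[0, 1\]) and `phase` (rad); see
#'   [default_coupling()].
#' @param swd_rate seizures per patient recording (default 2).
#' @param swd_duration_range seizure duration range in seconds
#'   (default c(11, 15), all strictly longer than the 10 s selection
#'   threshold).
#' @param swd_fundamental SWD fundamental frequency in Hz (default 3;
#'   must lie in the delta band).
#' @param swd_amplitude amplitude of the SWD waveform relative to the
#'   unit-variance background (default 6, so ictal windows are
#'   delta-dominated).
#' @param swd_background_atten multiplier applied to background activity
#'   inside a burst (default 0.1, suppressing the alpha rhythm during
#'   seizures).
#' @param leakage_matrix ROI x ROI instantaneous mixing matrix with unit
#'   diagonal; `NULL` means identity (no leakage).
#' @param seed master seed; every derived simulation is deterministic
#'   given it.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(sampling_rate = 300,
                             epoch_length = 120,
                             n_epochs_per_subject = 5,
                             n_patients = 33,
                             n_controls = 26,
                             band_amplitudes = default_band_amplitudes(),
                             posterior_alpha_gain = 2.5,
                             one_over_f_exponent = 1,
                             noise_sd = 1,
                             coupling_spec = default_coupling(),
                             swd_rate = 2,
                             swd_duration_range = c(11, 15),
                             swd_fundamental = 3,
                             swd_amplitude = 6,
                             swd_background_atten = 0.1,
                             leakage_matrix = NULL,
                             seed = 1L) {
  assert_that(sampling_rate >= 2 * 90,
              "sampling_rate must be at least 180 Hz (2 x 90 Hz band edge)")
  assert_that(epoch_length > 0 && n_epochs_per_subject >= 1,
              "epoch settings must be positive")
  assert_that(n_patients >= 0 && n_controls >= 0, "cohort sizes must be >= 0")
  bands <- canonical_bands()
  assert_that(is.matrix(band_amplitudes) &&
                all(bands$name %in% colnames(band_amplitudes)) &&
                all(c("control", "interictal", "ictal") %in%
                      rownames(band_amplitudes)),
              "band_amplitudes must be a regimes x bands matrix")
  if (nrow(coupling_spec) > 0) {
    assert_that(all(coupling_spec$strength >= 0 &
                      coupling_spec$strength <= 1),
                "coupling strengths must lie in [0, 1]")
    assert_that(all(coupling_spec$band %in% bands$name),
                "coupling_spec bands must be canonical band names")
  }
  delta <- bands[bands$name == "delta", ]
  assert_that(swd_fundamental >= delta$low && swd_fundamental <= delta$high,
              "swd_fundamental must lie within the delta band")
  assert_that(length(swd_duration_range) == 2L &&
                swd_duration_range[1] <= swd_duration_range[2] &&
                swd_duration_range[1] > 0,
              "swd_duration_range must be an increasing positive pair")
  if (!is.null(leakage_matrix)) {
    leakage_matrix <- as.matrix(leakage_matrix)
    assert_that(nrow(leakage_matrix) == ncol(leakage_matrix),
                "leakage matrix must be square")
    assert_that(max(abs(diag(leakage_matrix) - 1)) < 1e-12,
                "leakage matrix must have unit diagonal")
  }
  structure(
    list(sampling_rate = sampling_rate, epoch_length = epoch_length,
         n_epochs_per_subject = n_epochs_per_subject,
         n_patients = n_patients, n_controls = n_controls,
         band_amplitudes = band_amplitudes,
         posterior_alpha_gain = posterior_alpha_gain,
         one_over_f_exponent = one_over_f_exponent, noise_sd = noise_sd,
         coupling_spec = coupling_spec, swd_rate = swd_rate,
         swd_duration_range = swd_duration_range,
         swd_fundamental = swd_fundamental, swd_amplitude = swd_amplitude,
         swd_background_atten = swd_background_atten,
         leakage_matrix = leakage_matrix, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default per-regime carrier amplitudes
#'
#' Amplitudes (relative to the unit-variance 1/f background) of the
#' band-limited carriers, per regime. The interictal row raises delta and
#' lowers beta–gamma2 relative to controls, matching the qualitative
#' spectral signature of interictal absence-epilepsy recordings; the
#' `ictal` row parameterizes the background *between* seizures of a
#' patient recording (the in-seizure spectrum is dominated by the SWD
#' waveform itself and by `swd_background_atten`).
#'
#' @return A 3 x 6 numeric matrix, regimes by bands.
#' @export
default_band_amplitudes <- function() {
  m <- rbind(
    control    = c(delta = 0.60, theta = 0.50, alpha = 0.80,
                   beta = 0.50, gamma1 = 0.30, gamma2 = 0.20),
    interictal = c(delta = 1.10, theta = 0.60, alpha = 0.80,
                   beta = 0.35, gamma1 = 0.20, gamma2 = 0.12),
    ictal      = c(delta = 1.10, theta = 0.60, alpha = 0.80,
                   beta = 0.35, gamma1 = 0.20, gamma2 = 0.12)
  )
  m
}

#' Default envelope-coupling specification
#'
#' Beta-band amplitude-envelope coupling among posterior/frontal DMN
#' pairs, strengthening from control through interictal to ictal — the
#' ordering the connectivity stage is expected to recover. Carriers are
#' offset by pi/2 so leakage correction does not remove the coupling.
#'
#' @return Data frame with columns `regime`, `roi_a`, `roi_b`, `band`,
#'   `strength`, `phase`.
#' @export
default_coupling <- function() {
  pairs <- data.frame(
    roi_a = c("PCC.R", "MFC.R", "PCC.L"),
    roi_b = c("PCu.R", "IPL.R", "PCu.L")
  )
  strengths <- c(control = 0.15, interictal = 0.5, ictal = 0.8)
  out <- do.call(rbind, lapply(names(strengths), function(r)
    data.frame(regime = r, pairs, band = "beta",
               strength = unname(strengths[[r]]), phase = pi / 2)))
  rownames(out) <- NULL
  out
}

# Carrier frequency used for each canonical band (Hz).
band_carriers <- c(delta = 3, theta = 6, alpha = 10,
                   beta = 22, gamma1 = 45, gamma2 = 75)

# 1/f-coloured Gaussian noise via frequency-domain shaping.
one_over_f_noise <- function(n, exponent = 1, sd = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1L
  k_eff <- pmin(k, n - k)
  shape <- c(0, k_eff[-1L]^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# Slow (< ~1 Hz) positive envelope modulator: low-pass filtered Gaussian
# noise, rectified and scaled to unit mean. Generated at a low rate and
# interpolated to the target rate for numerical robustness.
slow_modulator <- function(n, fs, cutoff = 0.7) {
  lo_fs <- 10
  m <- ceiling(n / fs * lo_fs) + 8L
  z <- stats::rnorm(m)
  bf <- signal::butter(2, cutoff / (lo_fs / 2), type = "low")
  zf <- signal::filtfilt(bf, z)
  t_lo <- seq(0, by = 1 / lo_fs, length.out = m)
  t_hi <- seq(0, by = 1 / fs, length.out = n)
  e <- abs(stats::approx(t_lo, zf, xout = t_hi)$y)
  e / mean(e)
}

#' Simulate a spike-wave-discharge waveform
#'
#' Periodic spike-plus-slow-wave: a harmonic series of the fundamental
#' with 1/k amplitude decay, plus one sharp Gaussian-derivative transient
#' per cycle. The dominant spectral line sits at the fundamental. With
#' `n_harmonics = 1` the waveform degenerates to a pure sinusoid (no
#' spike transient).
#'
#' @param duration seconds (> 0).
#' @param fundamental fundamental frequency in Hz (classically 3).
#' @param sampling_rate Hz.
#' @param n_harmonics number of harmonics; `fundamental * n_harmonics`
#'   must stay below Nyquist.
#' @param spike_amplitude peak amplitude of the per-cycle transient
#'   (ignored when `n_harmonics == 1`).
#' @param spike_width transient width parameter (s).
#'
#' @return Numeric waveform of length `round(duration * sampling_rate)`,
#'   with attribute `spike_times` (seconds of each cycle's transient).
#' @export
simulate_swd <- function(duration, fundamental = 3, sampling_rate = 300,
                         n_harmonics = 5, spike_amplitude = 1.5,
                         spike_width = 0.012) {
  assert_that(duration > 0, "duration must be > 0")
  assert_that(fundamental * n_harmonics < sampling_rate / 2,
              "fundamental x n_harmonics must be below Nyquist")
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1L) / sampling_rate
  x <- rep(0, n)
  for (k in seq_len(n_harmonics)) {
    x <- x + cos(2 * pi * k * fundamental * t) / k
  }
  spike_times <- seq(0, duration - 1e-9, by = 1 / fundamental)
  if (n_harmonics > 1L) {
    for (tc in spike_times) {
      u <- (t - tc - 2 * spike_width) / spike_width
      # derivative-of-Gaussian pulse, peak-normalized
      x <- x + spike_amplitude * (-u * exp(0.5 - u^2 / 2))
    }
  }
  attr(x, "spike_times") <- spike_times
  x
}

# Deterministic-given-RNG SWD burst schedule guaranteeing, for the default
# rules, exactly `k` ictal windows and at least one qualifying clean span:
# the pre-span before the first burst and the tail span are kept > 90 s,
# interior gaps are kept < 90 s.
schedule_swd_bursts <- function(total, k, duration_range) {
  if (k == 0L) return(data.frame(onset = numeric(0), duration = numeric(0)))
  guard <- 95
  onsets <- numeric(k); durs <- numeric(k)
  onset <- guard + stats::runif(1, 0, 10)
  for (i in seq_len(k)) {
    onsets[i] <- onset
    durs[i] <- stats::runif(1, duration_range[1], duration_range[2])
    onset <- onsets[i] + durs[i] + stats::runif(1, 80, 88)
  }
  if (onsets[k] + durs[k] + guard > total) {
    stop(sprintf(paste("epoch budget too small: %d bursts with >90 s guard",
                       "spans need more than the %.0f s recording"),
                 k, total), call. = FALSE)
  }
  data.frame(onset = onsets, duration = durs)
}

#' Simulate 12-ROI source time series for one recording regime
#'
#' @param config a [synthetic_config()].
#' @param regime `"control"`, `"interictal"` or `"ictal"`.
#' @param seed integer seed (defaults to `config$seed`); identical seed
#'   and config give bit-identical output.
#' @param duration recording length in seconds; defaults to
#'   `epoch_length * n_epochs_per_subject`.
#' @param swd_schedule optional data frame (`onset`, `duration` in s)
#'   fixing burst placement for the ictal regime; `NULL` draws a schedule
#'   honouring the cohort construction guarantees.
#' @param subject_id,group metadata passed to the [recording()].
#' @param rois ROI set (default [make_roi_set()]).
#'
#' @return A 12-channel `recording`; ictal recordings carry `SWD`
#'   annotations.
#' @export
simulate_roi_timeseries <- function(config, regime = c("control",
                                                       "interictal",
                                                       "ictal"),
                                    seed = config$seed, duration = NULL,
                                    swd_schedule = NULL,
                                    subject_id = "s01",
                                    group = if (regime == "control")
                                      "control" else "patient",
                                    rois = make_roi_set()) {
  regime <- match.arg(regime)
  fs <- config$sampling_rate
  duration <- duration %||% (config$epoch_length *
                               config$n_epochs_per_subject)
  n <- round(duration * fs)
  set.seed(as.integer(seed))
  bands <- canonical_bands()
  posterior <- rois$region %in% c("PCC", "PCu", "IPL")
  amps <- config$band_amplitudes[regime, bands$name]

  if (regime == "ictal" && is.null(swd_schedule)) {
    swd_schedule <- schedule_swd_bursts(duration, config$swd_rate,
                                        config$swd_duration_range)
  }

  cp <- config$coupling_spec
  cp <- cp[cp$regime == regime, , drop = FALSE]

  # shared envelope modulators for coupled pairs, in spec order
  shared <- lapply(seq_len(nrow(cp)), function(i) slow_modulator(n, fs))

  t <- (seq_len(n) - 1L) / fs
  data <- matrix(0, nrow = nrow(rois), ncol = n)
  for (r in seq_len(nrow(rois))) {
    x <- one_over_f_noise(n, config$one_over_f_exponent, config$noise_sd)
    for (b in seq_len(nrow(bands))) {
      bname <- bands$name[b]
      a <- amps[[bname]]
      if (bname == "alpha" && posterior[r]) a <- a * config$posterior_alpha_gain
      if (a <= 0) next
      env <- slow_modulator(n, fs)
      phase <- stats::runif(1, 0, 2 * pi)
      hit <- which(cp$band == bname &
                     (cp$roi_a == rois$label[r] | cp$roi_b == rois$label[r]))
      if (length(hit) > 0L) {
        j <- hit[1L]
        cstr <- cp$strength[j]
        env <- (1 - cstr) * env + cstr * shared[[j]]
        env <- env / mean(env)
        # deterministic carrier phases so the pair offset is exactly cp$phase
        phase <- if (cp$roi_a[j] == rois$label[r]) 0 else cp$phase[j]
      }
      x <- x + a * env * cos(2 * pi * band_carriers[[bname]] * t + phase)
    }
    data[r, ] <- x
  }

  ann <- empty_annotations()
  if (regime == "ictal" && nrow(swd_schedule) > 0L) {
    gains <- 1 + stats::rnorm(nrow(rois), 0, 0.05)
    for (i in seq_len(nrow(swd_schedule))) {
      on <- swd_schedule$onset[i]; du <- swd_schedule$duration[i]
      idx <- which(t >= on & t < on + du)
      wave <- simulate_swd(length(idx) / fs, config$swd_fundamental, fs,
                           n_harmonics = 5)
      wave <- wave[seq_along(idx)]
      data[, idx] <- data[, idx] * config$swd_background_atten +
        config$swd_amplitude * (gains %o% wave)
    }
    ann <- data.frame(onset = swd_schedule$onset,
                      duration = swd_schedule$duration, label = "SWD")
  }

  if (!is.null(config$leakage_matrix)) {
    assert_that(nrow(config$leakage_matrix) == nrow(data),
                "leakage matrix dimension must match ROI count")
    data <- config$leakage_matrix %*% data
  }

  recording(data, fs, channel_labels = rois$label, annotations = ann,
            subject_id = subject_id, group = group)
}

#' Project source signals to sensors through a forward model
#'
#' Sensor data are `gain %*% sources` plus white Gaussian noise of the
#' stated standard deviation; annotations are copied through.
#'
#' @param sources a source-level `recording`.
#' @param forward a [forward_model()] whose gain has one column per
#'   source channel.
#' @param noise_sd sensor noise standard deviation (0 for noiseless).
#' @param seed optional seed for the sensor noise.
#' @return A sensor-level `recording`.
#' @export
mix_to_sensors <- function(sources, forward, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(sources, "recording"))
  g <- forward$gain
  assert_that(ncol(g) == nrow(sources$data),
              "forward gain column count must equal source channel count")
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- g %*% sources$data
  if (noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), 0, noise_sd),
                        nrow = nrow(out))
  }
  labs <- rownames(g) %||% sprintf("sens%03d", seq_len(nrow(g)))
  recording(out, sources$sampling_rate, channel_labels = labs,
            annotations = sources$annotations,
            subject_id = sources$subject_id, group = sources$group)
}

#' Cohort manifest for a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `seed` (the derived per-subject seed).
#' @export
cohort_manifest <- function(config) {
  ids <- c(sprintf("pat%02d", seq_len(config$n_patients)),
           sprintf("con%02d", seq_len(config$n_controls)))
  grp <- c(rep("patient", config$n_patients),
           rep("control", config$n_controls))
  data.frame(subject_id = ids, group = grp,
             seed = vapply(seq_along(ids),
                           function(i) derive_seed(config$seed, i),
                           integer(1)))
}

#' Simulate one cohort subject
#'
#' Patients are simulated in the ictal regime (interictal background with
#' scheduled SWD bursts placed so that, under the default selection
#' rules, each patient yields ictal and interictal segments by
#' construction); controls in the control regime.
#'
#' @param config a [synthetic_config()].
#' @param i subject index into [cohort_manifest()].
#' @param rois ROI set.
#' @return A `recording`.
#' @export
simulate_subject <- function(config, i, rois = make_roi_set()) {
  man <- cohort_manifest(config)
  assert_that(i >= 1L && i <= nrow(man), "subject index out of range")
  regime <- if (man$group[i] == "patient") "ictal" else "control"
  simulate_roi_timeseries(config, regime, seed = man$seed[i],
                          subject_id = man$subject_id[i],
                          group = man$group[i], rois = rois)
}

#' Generate a full synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @param rois ROI set.
#' @return List with `recordings` (list of `recording`s) and `manifest`
#'   (the [cohort_manifest()]).
#' @export
make_cohort <- function(config, rois = make_roi_set()) {
  total <- config$epoch_length * config$n_epochs_per_subject
  if (config$n_patients > 0) {
    # fail early, naming the constraint, rather than subject-by-subject
    need <- 2 * 95 + config$swd_rate * config$swd_duration_range[2] +
      max(0, config$swd_rate - 1) * 88
    assert_that(total >= need,
                sprintf(paste("epoch budget too small: %.0f s per subject",
                              "cannot hold %d seizures plus >90 s clean",
                              "spans (needs >= %.0f s)"),
                        total, config$swd_rate, need))
  }
  if (config$n_controls > 0) {
    assert_that(total >= 60,
                "epoch budget too small: controls need >= 60 s for two 30 s windows")
  }
  man <- cohort_manifest(config)
  recs <- lapply(seq_len(nrow(man)), function(i)
    simulate_subject(config, i, rois = rois))
  list(recordings = recs, manifest = man)
}
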