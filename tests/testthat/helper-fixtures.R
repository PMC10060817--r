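# Shared fixtures: everything is generated in code at test time.

no_coupling <- function() {
  data.frame(regime = character(0), roi_a = character(0),
             roi_b = character(0), band = character(0),
             strength = numeric(0), phase = numeric(0))
}

# A config sized for fast tests; the regime structure is unchanged.
small_config <- function(n_patients = 2, n_controls = 2, seed = 1L, ...) {
  synthetic_config(n_patients = n_patients, n_controls = n_controls,
                   epoch_length = 120, n_epochs_per_subject = 3,
                   seed = seed, ...)
}

# Recording with given annotations over constant (or supplied) data;
# handy for exercising the selection rules in isolation.
annotated_recording <- function(total_s, ann = NULL, fs = 100,
                                n_ch = 2, group = "patient",
                                data = NULL) {
  n <- round(total_s * fs)
  if (is.null(data)) {
    data <- matrix(sin(2 * pi * 7 * (1:n) / fs), nrow = n_ch, ncol = n,
                   byrow = TRUE)
  }
  if (is.null(ann)) {
    ann <- data.frame(onset = numeric(0), duration = numeric(0),
                      label = character(0))
  }
  recording(data, fs, channel_labels = sprintf("ch%d", 1:n_ch),
            annotations = ann, subject_id = "tst", group = group)
}

swd_ann <- function(onset, duration) {
  data.frame(onset = onset, duration = duration, label = "SWD")
}

art_ann <- function(onset, duration) {
  data.frame(onset = onset, duration = duration, label = "artifact")
}

# Narrowband test pair with explicit leakage mixing: y = beta * x + eps.
leakage_pair <- function(beta, seed, fs = 300, dur = 60,
                         band = c(8, 12)) {
  set.seed(seed)
  n <- dur * fs
  x <- 3 * bandpass(stats::rnorm(n), band, fs) + stats::rnorm(n, 0, 0.1)
  eps <- stats::rnorm(n, 0, 0.3)
  list(x = x, y = beta * x + eps)
}

# Simulate a single coupled pair via the generator and return its AEC-c.
coupled_pair_aecc <- function(strength, seed, dur = 60) {
  cp <- data.frame(regime = "control", roi_a = "PCC.R", roi_b = "PCu.R",
                   band = "beta", strength = strength, phase = pi / 2)
  cfg <- synthetic_config(coupling_spec = cp, seed = seed)
  rec <- simulate_roi_timeseries(cfg, "control", seed = seed,
                                 duration = dur)
  i <- match(c("PCC.R", "PCu.R"), rec$channel_labels)
  aecc_pair(rec$data[i[1], ], rec$data[i[2], ], c(15, 29),
            rec$sampling_rate)
}

# Independent step-up Benjamini-Hochberg oracle (direct definition).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Band-power measure table from control-regime recordings, for the
# statistics calibration tests.
measure_table <- function(cond_name, n_rec, seed0, dur = 60) {
  cfg <- synthetic_config(seed = 1L)
  rows <- lapply(seq_len(n_rec), function(i) {
    rec <- simulate_roi_timeseries(cfg, "control", seed = seed0 + i,
                                   duration = dur)
    sp <- relative_psd(welch_psd(rec))
    bp <- band_power(sp)
    data.frame(condition = cond_name, subject = paste0(cond_name, i),
               roi = bp$roi, band = bp$band, measure = "rel_power",
               value = bp$power)
  })
  do.call(rbind, rows)
}
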