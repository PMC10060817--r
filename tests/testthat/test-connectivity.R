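test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  fs <- 300
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  inside <- bandpass(x, c(8, 12), fs)
  keep <- (2 * fs):(18 * fs)
  expect_equal(sqrt(mean(inside[keep]^2)), sqrt(mean(x[keep]^2)),
               tolerance = 0.05)
  outside <- bandpass(x, c(15, 29), fs)
  expect_lt(sqrt(mean(outside[keep]^2)), 0.1 * sqrt(mean(x[keep]^2)))
  expect_true(all(bandpass(rep(0, 1000), c(8, 12), fs) == 0))
  expect_error(bandpass(x, c(60, 160), fs), "Nyquist")
})

test_that("orthogonalization removes exactly the zero-lag component", {
  set.seed(2)
  x <- rnorm(500)
  expect_equal(orthogonalize(2 * x, x), rep(0, 500), tolerance = 1e-12)
  z <- rnorm(500)
  z <- z - sum(z * x) / sum(x * x) * x   # construct <z, x> = 0
  expect_equal(orthogonalize(z, x), z, tolerance = 1e-12)
  expect_equal(orthogonalize(x + z, x), z, tolerance = 1e-10)
  expect_lt(abs(sum(orthogonalize(rnorm(500), x) * x)) /
              sqrt(sum(x^2)), 1e-8)
  expect_error(orthogonalize(x, rep(0, 500)), "all-zero")
})

test_that("the envelope recovers amplitudes and modulators", {
  fs <- 300
  t <- (0:(10 * fs - 1)) / fs
  env1 <- envelope(0.7 * cos(2 * pi * 10 * t))
  interior <- (fs):(9 * fs)
  expect_true(all(abs(env1[interior] - 0.7) < 0.02 * 0.7))
  mod <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  env2 <- envelope(mod * cos(2 * pi * 20 * t))
  expect_gt(cor(env2[interior], mod[interior]), 0.99)
  expect_true(all(envelope(rep(0, 100)) == 0))
})

test_that("pure leakage is suppressed while raw envelope correlation is not", {
  for (i in seq_along(c(0.2, 0.5, 0.9))) {
    beta <- c(0.2, 0.5, 0.9)[i]
    pair <- leakage_pair(beta, seed = 100 + i)
    v <- aecc_pair(pair$x, pair$y, c(8, 12), 300)
    expect_lt(abs(v), 0.1)
    xb <- bandpass(pair$x, c(8, 12), 300)
    yb <- bandpass(pair$y, c(8, 12), 300)
    keep <- 301:(length(xb) - 300)
    unc <- cor(envelope(xb)[keep], envelope(yb)[keep])
    if (beta >= 0.5) expect_gt(unc, 0.5)
  }
})

test_that("AEC-c is symmetric in its arguments and errors when too short", {
  set.seed(5)
  x <- rnorm(3000); y <- rnorm(3000)
  a <- aecc_pair(x, y, c(8, 12), 300)
  b <- aecc_pair(y, x, c(8, 12), 300)
  expect_identical(a, b)
  expect_error(aecc_pair(rnorm(200), rnorm(200), c(2, 4), 300),
               "10 cycles")
})

test_that("planted envelope coupling is recovered monotonically", {
  v <- vapply(c(0, 0.4, 0.8), coupled_pair_aecc, numeric(1), seed = 2)
  expect_true(all(diff(v) > 0))
  # coupled value beats the independent-channel null comfortably
  expect_gt(v[3], 0.3)
})

test_that("toy adjacency matrices give closed-form strengths", {
  a <- matrix(0.3, 12, 12); diag(a) <- 0
  cm <- connectivity_matrix(a, "beta")
  expect_equal(unname(cm$node_strength), rep(11 * 0.3, 12))
  expect_equal(unname(cm$relative_node_strength), rep(1 / 12, 12))
  # each node strength aggregates exactly 11 pairwise values
  expect_true(all(rowSums(cm$aecc != 0) == 11))
  row <- c(0, rep(0.1, 11))
  m <- matrix(0.1, 12, 12); diag(m) <- 0
  m[1, ] <- row; m[, 1] <- row
  expect_equal(unname(node_strength(connectivity_matrix(m))[1]), 1.1)
  # 3-node toy relative strengths
  t3 <- matrix(c(0, 0.5, 0.5, 0.5, 0, 0.5, 0.5, 0.5, 0), 3)
  t3[1, 2] <- t3[2, 1] <- 0.25; t3[1, 3] <- t3[3, 1] <- 0.75
  t3[2, 3] <- t3[3, 2] <- 0.75
  cm3 <- connectivity_matrix(t3)
  expect_equal(unname(relative_node_strength(cm3)),
               unname(rowSums(t3) / sum(rowSums(t3))))
  # zero total -> undefined relative strengths
  z <- connectivity_matrix(matrix(0, 3, 3))
  expect_true(all(is.na(relative_node_strength(z))))
})

test_that("the estimated adjacency is symmetric with the planted pair maximal", {
  cp <- data.frame(regime = "control", roi_a = "PCC.R", roi_b = "PCu.R",
                   band = "beta", strength = 0.85, phase = pi / 2)
  cfg <- synthetic_config(coupling_spec = cp, seed = 31)
  rec <- simulate_roi_timeseries(cfg, "control", seed = 31, duration = 60)
  cm <- adjacency(rec, canonical_bands()[4, ])
  expect_equal(max(abs(cm$aecc - t(cm$aecc))), 0)
  expect_true(all(diag(cm$aecc) == 0))
  i <- match(c("PCC.R", "PCu.R"), cm$labels)
  expect_equal(max(cm$aecc), cm$aecc[i[1], i[2]])
  expect_equal(sum(relative_node_strength(cm)), 1, tolerance = 1e-9)
  expect_error(adjacency(rec$data[1:5, ], c(15, 29), 300), "expected 12")
})

test_that("relabelling channels permutes the adjacency consistently", {
  cfg <- small_config(seed = 41)
  rec <- simulate_roi_timeseries(cfg, "control", seed = 41, duration = 40)
  cm <- adjacency(rec, canonical_bands()[3, ])
  perm <- sample(12)
  rec2 <- recording(rec$data[perm, ], rec$sampling_rate,
                    channel_labels = rec$channel_labels[perm])
  cm2 <- adjacency(rec2, canonical_bands()[3, ])
  expect_equal(cm2$aecc, cm$aecc[perm, perm], tolerance = 1e-10)
  expect_equal(cm2$node_strength, cm$node_strength[perm],
               tolerance = 1e-10)
})
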