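test_that("Kruskal-Wallis reproduces the worked rank example", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(7.2, df = 2, lower.tail = FALSE))
})

test_that("fully tied data give the H = 0 convention and empty groups error", {
  kw <- kruskal_wallis(list(rep(2, 4), rep(2, 5)))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("the chi-square p agrees with a permutation oracle", {
  set.seed(77)
  x <- rnorm(20); y <- rnorm(18)
  kw <- kruskal_wallis(list(x, y))
  pooled <- c(x, y)
  ranks <- rank(pooled)
  n <- length(pooled); n1 <- length(x)
  h_stat <- function(idx) {
    r1 <- sum(ranks[idx]); r2 <- sum(ranks) - r1
    12 / (n * (n + 1)) * (r1^2 / n1 + r2^2 / (n - n1)) - 3 * (n + 1)
  }
  perm <- replicate(10000, h_stat(sample(n, n1)))
  p_perm <- mean(perm >= kw$statistic - 1e-12)
  expect_lt(abs(p_perm - kw$p), 0.02)
})

test_that("Kruskal-Wallis is invariant to monotone transforms", {
  set.seed(9)
  for (i in 1:5) {
    g <- list(rnorm(6), rnorm(7, 0.5), rnorm(5, 1))
    a <- kruskal_wallis(g)$statistic
    b <- kruskal_wallis(lapply(g, function(v) exp(3 * v)))$statistic
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("BH correction follows the step-up rule on the worked examples", {
  r1 <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r1$reject))
  r2 <- fdr_bh(0.04)
  expect_equal(r2$q, 0.04)
  expect_true(r2$reject)
  r3 <- fdr_bh(c(0.5, 0.6, 0.9))
  expect_false(any(r3$reject))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with a brute-force step-up oracle on random vectors", {
  set.seed(123)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(fdr_bh(p)$q, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("the 2x2 chi-square matches hand-computed tables", {
  sex <- matrix(c(20, 13, 16, 10), 2)  # F/M by patient/control
  expect_equal(round(chi_square_2x2(sex)$statistic, 3), 0.005)
  expect_equal(chi_square_2x2(matrix(c(20, 20, 10, 10), 2))$statistic, 0,
               tolerance = 1e-12)
  # small-expected-count approximation warning is irrelevant to the statistic
  expect_equal(suppressWarnings(
    chi_square_2x2(matrix(c(5, 0, 0, 5), 2))$statistic), 10)
  expect_error(chi_square_2x2(matrix(c(5, 0, 0, 0), 2)), "margins")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("condition comparison flags a planted spectral effect", {
  # generator defaults plant higher delta power interictally than in
  # controls; a modest cohort should detect it in most ROIs
  ctrl <- measure_table("control", 10, seed0 = 500)
  inter <- local({
    cfg <- synthetic_config(seed = 1L)
    rows <- lapply(1:10, function(i) {
      rec <- simulate_roi_timeseries(cfg, "interictal", seed = 600 + i,
                                     duration = 60)
      sp <- relative_psd(welch_psd(rec))
      bp <- band_power(sp)
      data.frame(condition = "interictal", subject = paste0("i", i),
                 roi = bp$roi, band = bp$band, measure = "rel_power",
                 value = bp$power)
    })
    do.call(rbind, rows)
  })
  res <- compare_conditions(rbind(ctrl, inter),
                            contrasts = list(c("interictal", "control")))
  st <- res$stats
  delta <- st[st$contrast == "interictal_vs_control" &
                st$band == "delta", ]
  expect_gte(sum(delta$significant), 8)
  expect_true(all(delta$median_diff[delta$significant] > 0))
})

test_that("difference map of a condition against itself is zero", {
  tbl <- measure_table("control", 4, seed0 = 900)
  tbl2 <- tbl
  tbl2$condition <- "copy"
  tbl2$subject <- paste0("c", tbl2$subject)
  res <- compare_conditions(rbind(tbl, tbl2),
                            contrasts = list(c("control", "copy")))
  mp <- res$difference_maps[["rel_power.control_vs_copy"]]
  expect_true(all(mp == 0))
})

test_that("missing cells are excluded from the FDR family with a warning", {
  tbl <- measure_table("control", 3, seed0 = 950)
  other <- tbl[tbl$roi != "PCC.R", ]
  other$condition <- "B"
  other$subject <- paste0("b", other$subject)
  w <- capture_warnings(
    res <- compare_conditions(rbind(tbl, other),
                              contrasts = list(c("control", "B"))))
  expect_true(any(grepl("< 2 observations", w)))
  st <- res$stats
  miss <- st[st$roi == "PCC.R" & st$contrast == "control_vs_B", ]
  expect_true(all(is.na(miss$q_fdr)))
})

test_that("q-values never fall below raw p-values and flags match alpha", {
  set.seed(6)
  p <- runif(30)
  r <- fdr_bh(p, alpha = 0.05)
  expect_true(all(r$q >= p - 1e-12))
  expect_identical(r$reject, r$q < 0.05)
})
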