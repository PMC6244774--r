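test_that("band power recovers sinusoid power and obeys Parseval", {
  fs <- 250
  t <- seq_len(fs * 20) / fs
  bp <- band_power(sin(2 * pi * 10 * t), fs, c(0.5, 48))
  expect_equal(bp, 0.5, tolerance = 0.05) # amplitude^2 / 2

  expect_equal(band_power(rep(0, fs * 10), fs, c(0.5, 48)), 0)

  set.seed(1)
  wn <- rnorm(fs * 30)
  bp_full <- band_power(wn, fs, c(0, fs / 2))
  expect_equal(bp_full, var(wn), tolerance = 0.05)
})

test_that("band power scales quadratically with signal amplitude", {
  set.seed(2)
  cfg <- synth_config(n_regions = 2L, sampling_rate_hz = 250,
                      duration_s = 8)
  sig <- generate_region_timeseries(cfg, c(1, 2))
  p1 <- band_power(sig[, 1], 250)
  p2 <- band_power(sig[, 2], 250)
  expect_gt(p2, p1) # scale 2 beats scale 1
  # same signal, doubled amplitude: exactly 4x
  expect_equal(band_power(2 * sig[, 1], 250), 4 * p1, tolerance = 1e-10)
})

test_that("band power validates its inputs", {
  expect_error(band_power(rnorm(1000), 100, c(0.5, 60)), "Nyquist")
  expect_error(band_power(rnorm(4), 100, c(0.5, 40)), "too short")
})

test_that("box dilation matches counts and the brute-force oracle", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  mv <- mask_volume(m)
  expect_equal(sum(dilate_mask(mv, 1)$mask), 27) # 3x3x3
  expect_equal(sum(dilate_mask(mv, 2)$mask), 125) # 5x5x5
  expect_error(dilate_mask(mv, 0), "positive")

  set.seed(4)
  for (rep in 1:3) {
    r <- array(runif(6 * 7 * 5) < 0.12, c(6, 7, 5))
    if (!any(r)) r[2, 2, 2] <- TRUE
    dil <- dilate_mask(mask_volume(r), 1)
    expect_identical(dil$mask, brute_dilate(r))
    expect_true(all(dil$mask[r])) # output contains input
  }
})

test_that("peritumor region extraction matches a per-voxel scan", {
  set.seed(9)
  labs <- array(sample(0:5, 8^3, replace = TRUE), c(8, 8, 8))
  atlas <- labeled_volume(labs)
  m <- array(runif(8^3) < 0.1, c(8, 8, 8))
  m[1, 1, 1] <- TRUE
  mask <- mask_volume(m)
  got <- peritumor_regions(atlas, mask)
  oracle <- sort(unique(labs[m & labs > 0]))
  expect_equal(got, oracle)

  # mask over background only: empty set with warning
  bg <- array(FALSE, c(8, 8, 8))
  bg[which(labs == 0)[1]] <- TRUE
  expect_warning(empty <- peritumor_regions(atlas, mask_volume(bg)),
                 "no atlas region")
  expect_length(empty, 0)

  expect_error(peritumor_regions(atlas, mask_volume(array(TRUE, c(2, 2, 2)))),
               "shape")
})

test_that("activity scores are the stated means with the exact identity", {
  oba <- compute_oba(c(1, 2, 3, 4), peri = c(1, 2))
  expect_equal(oba$peritumor_raw, 1.5)
  expect_equal(oba$global_raw, 2.5)
  expect_equal(oba$nontumor_raw, 3.5)
  expect_equal(4 * oba$global_raw,
               2 * oba$peritumor_raw + 2 * oba$nontumor_raw)

  # uniform power: all three measures equal
  u <- compute_oba(rep(3.2, 10), peri = c(2, 5))
  expect_equal(c(u$peritumor_raw, u$global_raw, u$nontumor_raw),
               rep(3.2, 3))

  # weighted-mean identity on random instances
  set.seed(10)
  for (rep in 1:5) {
    p <- runif(12)
    peri <- sort(sample(12, sample(1:11, 1)))
    o <- compute_oba(p, peri)
    k <- length(peri)
    expect_equal(12 * o$global_raw,
                 k * o$peritumor_raw + (12 - k) * o$nontumor_raw)
  }

  expect_error(compute_oba(1:5, integer(0)), "no atlas region")
})

test_that("cohort z-scoring is exact, rank-preserving and errors on zero variance", {
  expect_equal(zscore_cohort(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(12)
  x <- rlnorm(30)
  z <- zscore_cohort(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(rank(z), rank(x))
  expect_error(zscore_cohort(rep(2, 5)), "zero variance")
})

test_that("reference z-scoring is affine and preserves the Cox HR up to SD scaling", {
  expect_equal(zscore_reference(5, 5, 2), 0)
  x <- c(0.2, -1, 3)
  expect_equal(zscore_reference(x, 0, 1), x)
  expect_error(zscore_reference(x, 0, 0), "positive")

  # affine re-referencing rescales the log-HR by the SD ratio
  set.seed(13)
  cfg <- synth_config(n_patients = 120, seed = 13)
  z <- rnorm(120)
  sv <- generate_survival(cfg, z)
  f1 <- cox_fit(sv$time_weeks, sv$event, z)
  zr <- zscore_reference(z, ref_mean = 0.7, ref_sd = 2)
  f2 <- cox_fit(sv$time_weeks, sv$event, zr)
  expect_equal(f2$coef[[1]], 2 * f1$coef[[1]], tolerance = 1e-6)
  expect_equal(f2$p_value[[1]], f1$p_value[[1]], tolerance = 1e-6)
})

test_that("rank tests agree on raw and cohort z-scored activity", {
  set.seed(14)
  raw <- rlnorm(21)
  z <- zscore_cohort(raw)
  grp <- rep(c("a", "b", "c"), c(12, 6, 3))
  h_raw <- kruskal_wallis(split(raw, grp))
  h_z <- kruskal_wallis(split(z, grp))
  expect_equal(h_raw$statistic, h_z$statistic)
  u_raw <- mann_whitney_u(raw[grp == "a"], raw[grp == "b"])
  u_z <- mann_whitney_u(z[grp == "a"], z[grp == "b"])
  expect_equal(u_raw$statistic, u_z$statistic)
  expect_equal(u_raw$p_value, u_z$p_value)
})
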