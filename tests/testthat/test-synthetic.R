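test_that("generators are deterministic under a fixed config and seed", {
  cfg <- synth_config(n_patients = 10, n_regions = 15,
                      grid_shape = c(14, 14, 14), seed = 101)
  a <- generate_cohort(cfg, volumes = TRUE)
  b <- generate_cohort(cfg, volumes = TRUE)
  expect_identical(a$patients, b$patients)
  expect_identical(a$atlas$labels, b$atlas$labels)
  expect_identical(lapply(a$masks, `[[`, "mask"),
                   lapply(b$masks, `[[`, "mask"))
})

test_that("generated atlas is a contiguous nonempty partition", {
  cfg <- synth_config(n_regions = 20L, grid_shape = c(16, 16, 16),
                      seed = 102)
  set.seed(cfg$seed)
  atlas <- generate_atlas(cfg)
  labs <- atlas$labels
  counts <- tabulate(labs[labs > 0], 20)
  expect_true(all(counts > 0)) # every region nonempty
  expect_equal(sum(counts), sum(labs > 0)) # volumes partition foreground

  # contiguity: flood fill from one voxel of each region covers the region
  dims <- dim(labs)
  for (r in sample(20, 5)) {
    vox <- which(labs == r)
    seen <- logical(length(labs))
    frontier <- vox[1]
    seen[frontier] <- TRUE
    nx <- dims[1]; nxy <- dims[1] * dims[2]
    while (length(frontier)) {
      nbrs <- c(outer(frontier, c(-1, 1, -nx, nx, -nxy, nxy), `+`))
      nbrs <- nbrs[nbrs >= 1 & nbrs <= length(labs)]
      nbrs <- nbrs[labs[nbrs] == r & !seen[nbrs]]
      seen[nbrs] <- TRUE
      frontier <- nbrs
    }
    expect_equal(sum(seen), length(vox))
  }

  # single-region config labels the whole foreground
  cfg1 <- synth_config(n_regions = 1L, grid_shape = c(8, 8, 8), seed = 103)
  set.seed(cfg1$seed)
  a1 <- generate_atlas(cfg1)
  expect_equal(sort(unique(as.vector(a1$labels))), c(0L, 1L))

  expect_error(synth_config(n_regions = 10, grid_shape = c(2, 2, 2)),
               "grid too small")
})

test_that("tumor masks are nonempty ellipsoids overlapping the atlas", {
  cfg <- synth_config(n_regions = 12, grid_shape = c(16, 16, 16),
                      seed = 104)
  set.seed(cfg$seed)
  atlas <- generate_atlas(cfg)
  for (rep in 1:5) {
    m <- generate_tumor_mask(cfg, atlas)
    expect_true(any(m$mask))
    expect_gte(length(peritumor_regions(atlas, m)), 1)
  }
  # unit radii: the discrete ball has at most 7 voxels
  set.seed(105)
  m1 <- generate_tumor_mask(cfg, atlas, radii_voxels = c(1, 1))
  expect_lte(sum(m1$mask), 7)
})

test_that("region time series track the activity scale monotonically", {
  cfg <- synth_config(n_regions = 2L, sampling_rate_hz = 250,
                      duration_s = 6)
  set.seed(106)
  wins <- replicate(30, {
    sig <- generate_region_timeseries(cfg, c(1, 2))
    band_power(sig[, 2], 250) > band_power(sig[, 1], 250)
  })
  expect_gte(mean(wins), 0.99)

  # doubling every amplitude quadruples expected band power (~10%)
  set.seed(107)
  ratios <- replicate(30, {
    s1 <- generate_region_timeseries(cfg, c(1, 1))[, 1]
    band_power(s1, 250)
  })
  set.seed(107)
  ratios2 <- replicate(30, {
    s2 <- generate_region_timeseries(cfg, c(2, 2))[, 1]
    band_power(s2, 250)
  })
  expect_equal(mean(ratios2) / mean(ratios), 4, tolerance = 0.1)

  expect_error(generate_region_timeseries(cfg, c(1, -1)), "positive")
  cfg0 <- synth_config(duration_s = 0.001, sampling_rate_hz = 250)
  expect_error(generate_region_timeseries(cfg0, rep(1, cfg0$n_regions)),
               "duration")
})

test_that("survival generator honours the hazard link and censoring rate", {
  # null link: event times independent of z across the z median split
  set.seed(108)
  ks_ok <- replicate(20, {
    cfg <- synth_config(n_patients = 200, log_hr_per_sd = 0,
                        censor_rate = 0, seed = sample.int(1e6, 1))
    z <- rnorm(200)
    sv <- generate_survival(cfg, z)
    suppressWarnings(ks.test(sv$time_weeks[z <= median(z)],
                             sv$time_weeks[z > median(z)])$p.value) > 0.01
  })
  expect_gte(mean(ks_ok), 0.9)

  # zero censor rate: all events observed
  cfg0 <- synth_config(n_patients = 50, censor_rate = 0, seed = 109)
  set.seed(109)
  sv0 <- generate_survival(cfg0, rnorm(50))
  expect_true(all(sv0$event == 1L))
  expect_true(all(sv0$time_weeks > 0))

  # configured censoring rate is approximately achieved
  cfgc <- synth_config(n_patients = 4000, censor_rate = 0.3, seed = 110)
  set.seed(110)
  svc <- generate_survival(cfgc, rnorm(4000))
  expect_equal(mean(svc$event == 0), 0.3, tolerance = 0.05)
})

test_that("NLGN3 tiers are monotone in activity with the target prevalences", {
  cfg <- synth_config(nlgn3_noise_sd = 0)
  set.seed(111)
  z <- sort(rnorm(50))
  tiers <- assign_nlgn3_tiers(cfg, z)
  # deterministic step function of z at zero noise
  ord <- match(tiers, c("low", "moderate", "high"))
  expect_true(all(diff(ord) >= 0))
  th <- cfg$nlgn3_thresholds
  expect_equal(tiers, c("low", "moderate", "high")[
    1 + (z > th[1]) + (z > th[2])])

  # default thresholds: expected tier counts ~= 12/6/3 out of 21
  cfgd <- synth_config()
  set.seed(112)
  zz <- rnorm(21 * 4000)
  tt <- assign_nlgn3_tiers(cfgd, zz)
  counts <- table(factor(tt, c("low", "moderate", "high"))) /
    length(zz) * 21
  expect_equal(unname(as.vector(counts)), c(12, 6, 3), tolerance = 0.05)

  # heavy noise destroys the tier-activity association
  cfgn <- synth_config(nlgn3_noise_sd = 50)
  set.seed(113)
  pvals <- replicate(30, {
    z <- rnorm(30)
    tiers <- assign_nlgn3_tiers(cfgn, z)
    if (length(unique(tiers)) < 2) return(NA_real_)
    kruskal_wallis(split(z, tiers))$p_value
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gt(mean(pvals > 0.05), 0.8)

  cfg_bad <- synth_config()
  cfg_bad$nlgn3_thresholds <- c(1, 0)
  expect_error(assign_nlgn3_tiers(cfg_bad, rnorm(5)), "increasing")
})

test_that("synthetic patient tables pass user-dialect validation", {
  cfg <- synth_config(n_patients = 16, n_regions = 20,
                      grid_shape = c(14, 14, 14), seed = 114)
  coh <- generate_cohort(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_patient_table(coh$patients, tmp)
  back <- load_patient_table(tmp, dialect = "user", quiet = TRUE)
  expect_equal(nrow(back), 16)
  expect_true(all(back$time_weeks > 0))
  # z-scores of global activity are cohort-standardised
  expect_lt(abs(mean(back$oba_global_z)), 1e-6)
  expect_equal(sd(back$oba_global_z), 1, tolerance = 1e-5)
})
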