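noiseless_cohort <- function(n = 4, extent = 120) {
  lapply(seq_len(n), function(k) {
    sl <- generate_slice(test_spec(noise_model = "none", infarct_extent = extent,
                                   seed = k))
    sl$slice_id <- sprintf("nl_%02d", k)
    sl
  })
}

test_that("summarize_outcomes reproduces the hand-computed CoV and its invariances", {
  out <- data.frame(
    slice_id = c("a", "a"), site_label = "s", factor_level = 1:2,
    measured_pct = c(12, 8), reference_pct = c(10, 10),
    error_pct_units = c(2, -2)
  )
  s <- summarize_outcomes(out)
  expect_equal(s$cov_mean, 100 * sd(c(2, -2)) / 10) # 28.284...
  expect_equal(s$mean_error, 0)
  expect_identical(s$roi_count, 2L)

  # all-zero errors
  z <- out; z$measured_pct <- 10; z$error_pct_units <- 0
  sz <- summarize_outcomes(z)
  expect_identical(sz$mean_error, 0)
  expect_identical(sz$cov_mean, 0)

  # adding a constant shifts the mean error, leaves CoV unchanged
  sh <- out; sh$error_pct_units <- sh$error_pct_units + 3
  ssh <- summarize_outcomes(sh)
  expect_equal(ssh$mean_error, s$mean_error + 3)
  expect_equal(ssh$cov_mean, s$cov_mean)

  # CoV is scale-consistent: doubling errors and reference leaves it unchanged
  d <- out
  d$error_pct_units <- d$error_pct_units * 2
  d$reference_pct <- d$reference_pct * 2
  expect_equal(summarize_outcomes(d)$cov_mean, s$cov_mean)
})

test_that("position study: noiseless cohort has zero error and zero CoV", {
  res <- run_position_study(noiseless_cohort())
  expect_identical(max(abs(res$outcomes$error_pct_units)), 0)
  expect_identical(res$summary$cov_mean, 0)
  expect_identical(res$summary$mean_error, 0)
  # 7 positions per slice on a 240-deg remote arc
  expect_true(all(table(res$outcomes$slice_id) == 7L))
})

test_that("a bias field inflates the position-study CoV (paired seeds)", {
  mk <- function(amp) {
    lapply(1:6, function(k) {
      sl <- generate_slice(test_spec(seed = 900 + k, bias_amplitude = amp,
                                     bias_scale = 10, bias_angle = 200,
                                     remote_sd = 0.015))
      sl$slice_id <- sprintf("b_%02d", k)
      sl
    })
  }
  cov_flat <- run_position_study(mk(0))$summary$cov_mean
  cov_bias <- run_position_study(mk(0.3))$summary$cov_mean
  expect_gt(cov_bias, cov_flat)
})

test_that("size study books ROI counts by what fits the remote arc", {
  res <- run_size_study(noiseless_cohort())
  expect_identical(res$summary$cov_mean, 0)
  # 240-deg arc fits all seven default sizes
  expect_true(all(table(res$outcomes$slice_id) == 7L))

  # narrow remote arc: extent 310 is excluded by the filter; use 170 -> arc 190
  res2 <- run_size_study(noiseless_cohort(extent = 170))
  expect_true(all(res2$outcomes$factor_level %in% seq(15, 105, by = 15)))
  expect_true(all(table(res2$outcomes$slice_id) == 7L))
})

test_that("n-SD study: 7 increasing thresholds per slice; separation makes n uncritical", {
  crisp <- lapply(1:3, function(k) {
    sl <- generate_slice(test_spec(seed = 40 + k, remote_mean = 0.1,
                                   remote_sd = 0.01, infarct_mean = 0.9,
                                   infarct_sd = 0.01))
    sl$slice_id <- sprintf("c_%02d", k)
    sl
  })
  res <- run_nsd_study(crisp)
  expect_true(all(table(res$outcomes$slice_id) == 7L))
  for (d in split(res$outcomes, res$outcomes$slice_id)) {
    expect_identical(d$factor_level, 2:8)
    expect_true(all(diff(d$threshold) > 0))
  }
  # n is uncritical when well separated: small errors (the residual is the
  # ~2.3% remote Gaussian tail picked up at n = 2, independent of sigma) and
  # a narrow measured range across n
  expect_lt(max(abs(res$outcomes$error_pct_units)), 2.5)
  for (d in split(res$outcomes, res$outcomes$slice_id)) {
    expect_lt(diff(range(d$measured_pct)), 2.5)
  }

  # overlapping distributions: measured size falls steeply over n = 2..8
  overlap <- lapply(1:3, function(k) {
    sl <- generate_slice(test_spec(seed = 50 + k, remote_mean = 0.15,
                                   remote_sd = 0.03, infarct_mean = 0.27,
                                   infarct_sd = 0.06))
    sl$slice_id <- sprintf("o_%02d", k)
    sl
  })
  res2 <- run_nsd_study(overlap)
  for (d in split(res2$outcomes, res2$outcomes$slice_id)) {
    m <- d$measured_pct[order(d$factor_level)]
    expect_true(all(diff(m) <= 0))
    expect_lt(m[7], 0.5 * m[1])
  }
})

test_that("spurious comparison is paired and one-sided", {
  # noiseless: no islands, difference exactly zero
  res0 <- run_spurious_comparison(noiseless_cohort())
  expect_identical(res0$paired_mean_diff, 0)

  # noisy, low-contrast cohort: naive >= no-spurious on every slice
  noisy <- lapply(1:5, function(k) {
    sl <- generate_slice(test_spec(seed = 60 + k, remote_mean = 0.15,
                                   remote_sd = 0.035, infarct_mean = 0.3,
                                   infarct_sd = 0.08))
    sl$slice_id <- sprintf("n_%02d", k)
    sl
  })
  res <- run_spurious_comparison(noisy)
  w <- reshape(res$outcomes[, c("slice_id", "variant", "measured_pct")],
               direction = "wide", idvar = "slice_id", timevar = "variant")
  expect_true(all(w$measured_pct.naive >= w$measured_pct.no_spurious))

  # salt-noise construction with a known island census
  sl <- generate_slice(test_spec(noise_model = "none"))
  img <- sl$image
  polar <- polar_parameterize(sl$endo_contour, sl$epi_contour, sl$myo_mask)
  remote_px <- which(sl$myo_mask & !sl$truth_infarct_mask &
                       angle_dist(polar$theta, 270) < 30)
  salt <- remote_px[seq(1, length(remote_px), by = 7)][1:8] # 8 isolated pixels
  img[salt] <- 0.9
  fix <- mid_remote_roi(sl)
  naive <- segment_slice(img, sl$myo_mask, fix$roi, seg_params(5))
  clean <- segment_slice(img, sl$myo_mask, fix$roi, seg_params(5, remove_spurious = TRUE))
  census <- oracle_components(naive$infarct_mask, 8L)
  expected_removed <- sum(census$sizes[census$sizes < 10L])
  expect_identical(clean$removed_pixels, expected_removed)
  expect_identical(sum(naive$infarct_mask) - sum(clean$infarct_mask), expected_removed)
})

test_that("optimal_n_per_slice recovers a constructed optimum and flags degeneracy", {
  sl <- generate_slice(test_spec(seed = 77, remote_mean = 0.15, remote_sd = 0.02,
                                 infarct_mean = 0.25, infarct_sd = 0.08))
  fix <- mid_remote_roi(sl)
  st <- remote_stats(sl$image, fix$roi)
  for (n0 in c(2, 4, 6)) {
    ref_mask <- classify(sl$image, sl$myo_mask, nsd_threshold(st, n0))
    ref_pct <- infarct_fraction(ref_mask, sl$myo_mask)
    opt <- optimal_n_per_slice(sl$image, sl$myo_mask, fix$roi, ref_pct)
    expect_lte(abs(opt$n_star - n0), 0.1 + 1e-9)
  }
  expect_error(optimal_n_per_slice(sl$image, sl$myo_mask, fix$roi, 0), "positive")

  # near-invisible infarct: optimum pinned at a grid end and flagged
  inv <- generate_slice(test_spec(seed = 78, remote_mean = 0.15, remote_sd = 0.02,
                                  infarct_mean = 0.150001, infarct_sd = 0))
  fi <- mid_remote_roi(inv)
  oi <- optimal_n_per_slice(inv$image, inv$myo_mask, fi$roi,
                            infarct_fraction(inv$truth_infarct_mask, inv$myo_mask))
  expect_true(oi$degenerate)
})

test_that("higher-sigma sites need a lower optimal n at matched contrast", {
  mk <- function(sdval, label) {
    list(template = list(grid_size = 96L, infarct_extent = 120, remote_sd = sdval,
                         remote_mean = 0.15, infarct_mean = 0.3, infarct_sd = 0.05,
                         site_label = label),
         count = 12L, label = label)
  }
  coh <- generate_cohort(list(mk(0.013, "low_sd"), mk(0.026, "high_sd")), 202L)
  res <- run_optimal_n_study(coh)
  m <- setNames(res$per_site$mean, res$per_site$site_label)
  expect_gt(m[["low_sd"]], m[["high_sd"]])
})

test_that("signal variability report recovers injected group structure", {
  # noiseless: zero variability in every group
  rep0 <- signal_variability_report(noiseless_cohort())
  expect_true(all(rep0$per_group$mean == 0))

  # fixed [0, 1] image range: reported sigma matches injected remote_sd
  mk_fixed <- function(k) {
    sl <- generate_slice(test_spec(seed = 300 + k, remote_sd = 0.02))
    sl$image[1, 1] <- 1 # pin the normalization range to [0, 1]
    sl$slice_id <- sprintf("f_%02d", k)
    sl
  }
  repf <- signal_variability_report(lapply(1:10, mk_fixed))
  expect_lt(abs(repf$per_group$mean - 0.02), 0.002)

  # two-site cohort at vendor-realistic sigmas: ordering and ~2x ratio
  mk_site <- function(sdval, label) {
    list(template = list(grid_size = 96L, infarct_extent = 120, remote_sd = sdval),
         count = 15L, label = label)
  }
  coh <- generate_cohort(list(mk_site(0.013, "lo"), mk_site(0.026, "hi")), 77L)
  rep2 <- signal_variability_report(coh)
  m <- setNames(rep2$per_group$mean, rep2$per_group$site_label)
  expect_gt(m[["hi"]], m[["lo"]])
  expect_gt(m[["hi"]] / m[["lo"]], 1.6)
  expect_lt(m[["hi"]] / m[["lo"]], 2.4)

  flat <- noiseless_cohort(1)[[1]]
  flat$image[] <- 0.3
  expect_error(signal_variability_report(list(flat)), "constant image")
})

test_that("studies are deterministic end to end", {
  coh <- lapply(1:4, function(k) {
    sl <- generate_slice(test_spec(seed = 800 + k))
    sl$slice_id <- sprintf("d_%02d", k)
    sl
  })
  r1 <- run_nsd_study(coh)
  r2 <- run_nsd_study(coh)
  expect_identical(r1$outcomes, r2$outcomes)
})
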