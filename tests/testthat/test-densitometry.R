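# Histogram construction and per-subject densitometry statistics.

test_that("degenerate and hand-computed histograms give exact statistics", {
  # single bin: SD 0, thresholds collapse onto the mean, both tails empty
  h1 <- attenuation_histogram(-800L, 10, 8)
  r1 <- compute_densitometry(h1)
  expect_equal(r1$mean_hu, -800)
  expect_equal(r1$sd_hu, 0)
  expect_equal(r1$lat_hu, -800)
  expect_equal(r1$hat_hu, -800)
  expect_equal(r1$pct_low, 0)
  expect_equal(r1$pct_high, 0)
  expect_equal(r1$tlc_ct_mL, 10 * 8 / 1000)

  # two equal bins at -900 / -700: mean -800, population SD 100, thresholds
  # land exactly on the bins, and the strict inequalities exclude them
  h2 <- attenuation_histogram(c(-900L, -700L), c(500, 500), 1)
  r2 <- compute_densitometry(h2)
  expect_equal(r2$mean_hu, -800)
  expect_equal(r2$sd_hu, 100)
  expect_equal(r2$lat_hu, -900)
  expect_equal(r2$hat_hu, -700)
  expect_equal(r2$pct_low, 0)
  expect_equal(r2$pct_high, 0)
  expect_equal(r2$min_hu, -900L)
  expect_equal(r2$max_hu, -700L)
})

test_that("build_histogram tabulates masked voxels exactly", {
  vol <- attenuation_volume(array(-800L, c(4, 4, 4)), c(2, 2, 2))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:10] <- TRUE
  h <- build_histogram(vol, lung_mask(mask))
  expect_equal(h$bin_values, -800L)
  expect_equal(h$counts, 10)
  expect_equal(h$voxel_volume_mm3, 8)
  expect_error(build_histogram(vol, lung_mask(array(FALSE, c(4, 4, 4)))),
               class = "pedct_empty_mask")
})

test_that("histogram path equals the brute-force voxel oracle", {
  ph <- small_phantom(seed = 17)
  res <- densitometry_from_volume(ph$volume, ph$ground_truth_mask)
  oracle <- brute_force_densitometry(ph$volume, ph$ground_truth_mask)
  for (f in names(oracle)) {
    denom <- max(1, abs(oracle[[f]]))
    expect_lt(abs(res[[f]] - oracle[[f]]) / denom, 1e-9, label = f)
  }
  # and the composition contract holds exactly
  expect_identical(res,
                   compute_densitometry(build_histogram(ph$volume,
                                                        ph$ground_truth_mask)))
})

test_that("histogram total is consistent with mask volume across modules", {
  ph <- small_phantom(seed = 23)
  h <- build_histogram(ph$volume, ph$ground_truth_mask)
  expect_equal(sum(h$counts), sum(ph$ground_truth_mask$voxels))
  expect_equal(sum(h$counts) * h$voxel_volume_mm3,
               mask_volume_mL(ph$ground_truth_mask, ph$volume) * 1000)
  expect_equal(compute_densitometry(h)$tlc_ct_mL, ph$ground_truth_volume_mL)
})

test_that("translation equivariance: shifting HU shifts mean and thresholds
           and leaves SD and tail fractions unchanged", {
  ph <- small_phantom(seed = 29)
  h <- build_histogram(ph$volume, ph$ground_truth_mask)
  base <- compute_densitometry(h)
  for (shift in c(-37L, 50L)) {
    r <- compute_densitometry(attenuation_histogram(h$bin_values + shift,
                                                    h$counts,
                                                    h$voxel_volume_mm3))
    expect_equal(r$mean_hu, base$mean_hu + shift, tolerance = 1e-12)
    expect_equal(r$lat_hu, base$lat_hu + shift, tolerance = 1e-12)
    expect_equal(r$hat_hu, base$hat_hu + shift, tolerance = 1e-12)
    expect_equal(r$sd_hu, base$sd_hu, tolerance = 1e-12)
    expect_equal(r$pct_low, base$pct_low)
    expect_equal(r$pct_high, base$pct_high)
  }
})

test_that("symmetric histograms have equal tail fractions", {
  vals <- c(-900L, -850L, -800L, -750L, -700L)
  counts <- c(100, 200, 400, 200, 100)
  r <- compute_densitometry(attenuation_histogram(vals, counts, 8))
  expect_equal(r$pct_low, r$pct_high)
  expect_equal(r$mean_hu, -800)
})

test_that("large calibrated samples reproduce the reference targets", {
  d <- fixture_dist()
  x <- sample_parenchyma(d, 1e6, seed = 404)
  h <- table(x)
  r <- compute_densitometry(attenuation_histogram(as.integer(names(h)),
                                                  as.numeric(h), 8))
  expect_lt(abs(r$mean_hu - (-803)), 1)
  expect_lt(abs(r$sd_hu - 147.3), 1)
  expect_lt(abs(r$pct_low - 0.53), 0.15)
  expect_lt(abs(r$pct_high - 10.20), 0.35)
})

test_that("reporting precision rounds to 0.1 HU and 0.01 percent", {
  h <- attenuation_histogram(c(-812L, -799L, -780L), c(3, 5, 2), 8)
  f <- format_densitometry(compute_densitometry(h))
  expect_equal(f$mean_hu, round(f$mean_hu, 1))
  expect_equal(f$pct_low, round(f$pct_low, 2))
})

test_that("histogram CSV round-trips", {
  ph <- small_phantom(seed = 31)
  h <- build_histogram(ph$volume, ph$ground_truth_mask)
  path <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, path)
  h2 <- read_histogram_csv(path)
  expect_identical(h2$bin_values, h$bin_values)
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$voxel_volume_mm3, h$voxel_volume_mm3)
  expect_identical(compute_densitometry(h2), compute_densitometry(h))
})

test_that("histogram invariants are enforced", {
  expect_error(attenuation_histogram(c(-800L, -800L), c(1, 1), 8),
               class = "pedct_bad_histogram")
  expect_error(attenuation_histogram(c(-800L, -700L), c(0, 0), 8),
               class = "pedct_bad_histogram")
  expect_error(attenuation_histogram(-800L, 1, 0),
               class = "pedct_bad_histogram")
})
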