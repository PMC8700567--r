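# Parenchymal distribution calibration, phantom generation, cohort generation.

test_that("calibration hits reference targets and records achieved values", {
  targets <- list(
    # age-group medians: mean, SD (mean minus low threshold), %low, %high
    c(-803, 147.3, 0.0053, 0.1020),   # 10-year-old
    c(-730, 142.3, 0.0146, 0.1247),   # 6-year-old (LAT median -872.3)
    c(-832.5, 126.9, 0.0069, 0.0950)) # 15-year-old
  for (tg in targets) {
    d <- calibrate_distribution(tg[1], tg[2], tg[3], tg[4])
    expect_s3_class(d, "parenchyma_distribution")
    expect_equal(d$achieved_mean, tg[1], tolerance = 0.5 / abs(tg[1]))
    expect_equal(d$achieved_sd, tg[2], tolerance = 0.5 / tg[2])
    expect_lt(abs(d$achieved_frac_low - tg[3]), 0.003)
    expect_lt(abs(d$achieved_frac_high - tg[4]), 0.003)
    expect_true(d$tail_weight >= 0 && d$tail_weight <= 0.5)
    expect_gt(d$tail_scale, 0)
    expect_lt(d$achieved_frac_low + d$achieved_frac_high, 1)
  }
})

test_that("calibration is deterministic (no sampling involved)", {
  d1 <- calibrate_distribution(-803, 147.3, 0.0053, 0.1020)
  d2 <- calibrate_distribution(-803, 147.3, 0.0053, 0.1020)
  expect_identical(d1, d2)
})

test_that("symmetric Gaussian targets collapse the tail", {
  gauss_tail <- pnorm(-1)  # one-sided mass beyond 1 SD, ~0.158655
  d <- calibrate_distribution(-800, 150, gauss_tail, gauss_tail)
  expect_lt(d$tail_weight, 0.01)
  expect_equal(d$achieved_frac_low, gauss_tail, tolerance = 1e-3)
  expect_equal(d$achieved_frac_high, gauss_tail, tolerance = 1e-3)
})

test_that("calibration round-trip: numerical integration of the density
           reproduces the achieved moments and fractions", {
  d <- fixture_dist()
  dens <- function(x) {
    (1 - d$tail_weight) * dnorm(x, d$bulk_mean, d$bulk_sd) +
      d$tail_weight * ifelse(x >= d$bulk_mean,
                             exp(-(x - d$bulk_mean) / d$tail_scale) /
                               d$tail_scale, 0)
  }
  lo <- d$bulk_mean - 12 * d$bulk_sd
  hi <- d$bulk_mean + 40 * d$tail_scale
  m <- integrate(function(x) x * dens(x), lo, hi, subdivisions = 2000L,
                 rel.tol = 1e-10)$value
  v <- integrate(function(x) (x - m)^2 * dens(x), lo, hi,
                 subdivisions = 2000L, rel.tol = 1e-10)$value
  expect_equal(m, d$achieved_mean, tolerance = 1e-6)
  expect_equal(sqrt(v), d$achieved_sd, tolerance = 1e-6)
  frac_low <- integrate(dens, lo, m - sqrt(v), subdivisions = 2000L,
                        rel.tol = 1e-10)$value
  frac_high <- integrate(dens, m + sqrt(v), hi, subdivisions = 2000L,
                         rel.tol = 1e-10)$value
  expect_equal(frac_low, d$achieved_frac_low, tolerance = 1e-6)
  expect_equal(frac_high, d$achieved_frac_high, tolerance = 1e-6)
})

test_that("empirical moments of large samples match achieved values", {
  d <- fixture_dist()
  n <- 1e6
  x <- sample_parenchyma(d, n, seed = 101)
  # 3 Monte-Carlo standard errors, plus a 1-HU-bin discretisation allowance
  # on the tail fractions (samples are rounded to integer HU).
  se_mean <- d$achieved_sd / sqrt(n)
  expect_lt(abs(mean(x) - d$achieved_mean), 3 * se_mean + 0.05)
  expect_lt(abs(sd(x) - d$achieved_sd) / d$achieved_sd, 0.01)
  lat <- mean(x) - sd(x); hat <- mean(x) + sd(x)
  for (pair in list(c(mean(x < lat), d$achieved_frac_low),
                    c(mean(x > hat), d$achieved_frac_high))) {
    se <- sqrt(pair[2] * (1 - pair[2]) / n)
    expect_lt(abs(pair[1] - pair[2]), 3 * se + 0.001)
  }
})

test_that("invalid calibration targets are rejected", {
  expect_error(calibrate_distribution(-800, -5, 0.01, 0.1), "target_sd")
  expect_error(calibrate_distribution(-800, 150, 0.2, 0.1), "frac")
  expect_error(calibrate_distribution(-800, 150, 0, 0.1), "frac")
})

test_that("parenchyma_distribution validates its invariants", {
  expect_error(parenchyma_distribution(-800, 0, 0.1, 100), "bulk_sd")
  expect_error(parenchyma_distribution(-800, 50, 0.7, 100), "tail_weight")
  expect_error(parenchyma_distribution(-800, 50, 0.1, -1), "tail_scale")
})

test_that("phantom ground-truth volume is voxel count times voxel volume", {
  # two disjoint ellipsoids at 1 mm isotropic spacing: volume in mL equals
  # lung voxel count / 1000
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing = c(1, 1, 1),
                       distribution = fixture_dist(),
                       lung_ellipsoids = list(
                         list(center = c(20, 20, 13), semiaxes = c(10, 8, 5)),
                         list(center = c(20, 20, 28), semiaxes = c(10, 8, 5))))
  ph <- generate_phantom(spec, seed = 5)
  expect_equal(ph$ground_truth_volume_mL,
               sum(ph$ground_truth_mask$voxels) / 1000)
  expect_equal(ph$ground_truth_mask$component_count, 2L)
})

test_that("phantoms are bit-identical for identical spec and seed", {
  a <- small_phantom(seed = 33)
  b <- small_phantom(seed = 33)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$ground_truth_mask$voxels, b$ground_truth_mask$voxels)
  c <- small_phantom(seed = 34)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("phantom lung voxels follow the calibrated distribution", {
  ph <- generate_phantom(
    phantom_spec(grid_shape = c(128, 128, 128), spacing = c(2, 2, 2),
                 distribution = fixture_dist(),
                 lung_ellipsoids = list(
                   list(center = c(64.5, 64.5, 38), semiaxes = c(60, 46, 24)),
                   list(center = c(64.5, 64.5, 91), semiaxes = c(60, 46, 24)))),
    seed = 9)
  n_lung <- sum(ph$ground_truth_mask$voxels)
  expect_gt(n_lung, 5e5)
  vals <- ph$volume$voxels[ph$ground_truth_mask$voxels]
  expect_lt(abs(mean(vals) - (-803)), 1)
})

test_that("lung ellipsoids escaping the body are rejected", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32),
                       distribution = fixture_dist(),
                       lung_ellipsoids = list(
                         list(center = c(16, 16, 2), semiaxes = c(10, 10, 6))))
  expect_error(generate_phantom(spec, seed = 1), "outside the body",
               class = "pedct_bad_spec")
})

test_that("noise-free cohorts lie exactly on the reference curves", {
  coh <- noise_free_cohort(n = 12)
  eqs <- reference_set()
  expect_setequal(coh$age_years, 6:17)
  expect_equal(coh$tlc_ct_ml,
               predict(eqs[["tlc_ct_ml~age_years"]], coh$age_years),
               tolerance = 1e-9)
  expect_equal(coh$mean_hu,
               predict(eqs[["mean_hu~age_years"]], coh$age_years),
               tolerance = 1e-9)
  expect_equal(coh$lat_hu,
               predict(eqs[["lat_hu~age_years"]], coh$age_years),
               tolerance = 1e-9)
  expect_equal(coh$hat_hu,
               predict(eqs[["hat_hu~age_years"]], coh$age_years),
               tolerance = 1e-9)
  expect_equal(coh$pct_high,
               predict(eqs[["pct_high~age_years"]], coh$age_years),
               tolerance = 1e-9)
  expect_equal(coh$pct_low,
               predict(eqs[["pct_low~tlc_ct_ml"]], coh$tlc_ct_ml),
               tolerance = 1e-9)
  # age-6 record sits at -892.8 + 1160.4/6
  expect_equal(coh$mean_hu[coh$age_years == 6], -699.4, tolerance = 1e-9)
})

test_that("cohort generation is reproducible and honors its cohort_spec", {
  a <- generate_cohort(cohort_spec(n_subjects = 40, seed = 7))
  b <- generate_cohort(cohort_spec(n_subjects = 40, seed = 7))
  expect_identical(a, b)
  expect_true(all(a$age_years >= 6 & a$age_years <= 17))
  expect_true(all(a$lat_hu <= a$mean_hu & a$mean_hu <= a$hat_hu))
  expect_true(all(a$tlc_ct_ml > 0))
  # two noise-free subjects of the same age are identical apart from the id
  two <- generate_cohort(cohort_spec(n_subjects = 2, age_min = 10,
                                     age_max = 10, seed = 1,
                                     noise_sd_attenuation = 0,
                                     noise_sd_tlc = 0, noise_sd_pct = 0))
  expect_equal(two[1, -1], two[2, -1], ignore_attr = TRUE)
})

test_that("unknown reference set identifier is rejected", {
  expect_error(generate_cohort(cohort_spec(reference_set = "nope")),
               "unknown reference_set",
               class = "pedct_unknown_reference_set")
})

test_that("simulation recovery: noisy cohort refits recover the generating
           inverse model within 2 standard errors", {
  coh <- generate_cohort(cohort_spec(n_subjects = 80, seed = 2024))
  fit <- fit_inverse(coh$age_years, coh$mean_hu)
  expect_lt(abs(fit$a - (-892.8)), 2 * fit$se_a)
  expect_lt(abs(fit$b - 1160.4), 2 * fit$se_b)
})

test_that("generators never touch the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(small_phantom(seed = 3))
  invisible(generate_cohort(cohort_spec(n_subjects = 5, seed = 3)))
  invisible(sample_parenchyma(fixture_dist(), 10, seed = 3))
  expect_identical(.Random.seed, before)
})
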