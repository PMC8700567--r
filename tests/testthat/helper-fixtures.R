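# Shared fixtures, built in code. The calibrated distribution is cached per
# session because calibration is deterministic and several files use it.

.fixture_cache <- new.env(parent = emptyenv())

# Mixture calibrated to the 10-year-old reference medians: mean -803 HU,
# SD 147.3 HU (= mean minus the low threshold -950.3), tail fractions
# 0.53% / 10.20%.
fixture_dist <- function() {
  if (is.null(.fixture_cache$dist))
    .fixture_cache$dist <- calibrate_distribution(-803, 147.3, 0.0053, 0.1020)
  .fixture_cache$dist
}

# Small fast phantom (32^3 at 2 mm) for structural tests.
small_phantom <- function(seed = 11, ...) {
  generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                spacing = c(2, 2, 2),
                                distribution = fixture_dist(), ...),
                   seed = seed)
}

# Default-scale phantom (96^3 at 2 mm), the stated desk-scale geometry.
default_phantom <- function(seed = 11, ...) {
  generate_phantom(phantom_spec(distribution = fixture_dist(), ...),
                   seed = seed)
}

noise_free_cohort <- function(n = 12, seed = 1, age_assignment = "cycle") {
  generate_cohort(cohort_spec(n_subjects = n, seed = seed,
                              noise_sd_attenuation = 0, noise_sd_tlc = 0,
                              noise_sd_pct = 0,
                              age_assignment = age_assignment))
}

# Independent brute-force densitometry oracle: plain arithmetic on the raw
# masked voxel values, no histogram involved.
brute_force_densitometry <- function(volume, mask) {
  vals <- as.numeric(volume$voxels[mask$voxels])
  n <- length(vals)
  m <- sum(vals) / n
  s <- sqrt(sum((vals - m)^2) / n)
  list(tlc_ct_mL = n * prod(volume$spacing) / 1000,
       mean_hu = m, sd_hu = s, lat_hu = m - s, hat_hu = m + s,
       pct_low = 100 * sum(vals < m - s) / n,
       pct_high = 100 * sum(vals > m + s) / n)
}
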