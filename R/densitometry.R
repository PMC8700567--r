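#' Attenuation histogram
#'
#' Frequencies of integer HU values over the masked lung voxels, with the
#' voxel volume needed to convert counts to millilitres. Bins have width
#' 1 HU; only observed values are stored.
#'
#' @param bin_values strictly increasing integer HU values.
#' @param counts non-negative voxel counts per bin; total must be > 0.
#' @param voxel_volume_mm3 volume of one voxel in cubic millimetres.
#' @return Object of class `attenuation_histogram`.
#' @export
attenuation_histogram <- function(bin_values, counts, voxel_volume_mm3) {
  bin_values <- as.integer(bin_values)
  counts <- as.numeric(counts)
  if (length(bin_values) != length(counts))
    stop_pedct("bin_values and counts lengths differ", "pedct_bad_histogram")
  if (is.unsorted(bin_values, strictly = TRUE))
    stop_pedct("bin_values must be strictly increasing", "pedct_bad_histogram")
  if (any(counts < 0) || sum(counts) <= 0)
    stop_pedct("counts must be >= 0 with positive total", "pedct_bad_histogram")
  if (voxel_volume_mm3 <= 0)
    stop_pedct("voxel_volume_mm3 must be > 0", "pedct_bad_histogram")
  structure(list(bin_values = bin_values, counts = counts,
                 voxel_volume_mm3 = as.numeric(voxel_volume_mm3)),
            class = "attenuation_histogram")
}

#' @export
print.attenuation_histogram <- function(x, ...) {
  cat("<attenuation_histogram> ", length(x$bin_values), " bins, ",
      format(sum(x$counts), big.mark = ","), " voxels, HU [",
      min(x$bin_values), ", ", max(x$bin_values), "]\n", sep = "")
  invisible(x)
}

#' Build the attenuation histogram of masked voxels
#'
#' Tabulates the integer HU values of all voxels selected by the mask into
#' width-1 bins.
#'
#' @param volume an [attenuation_volume()].
#' @param mask a congruent, nonempty [lung_mask()].
#' @return An [attenuation_histogram()] whose total count equals the number
#'   of masked voxels and whose `voxel_volume_mm3` is the product of the
#'   volume's spacings.
#' @export
build_histogram <- function(volume, mask) {
  check_congruent(volume, mask)
  vals <- volume$voxels[mask$voxels]
  if (length(vals) == 0)
    stop_pedct("mask selects no voxels", "pedct_empty_mask")
  tab <- table(vals)
  attenuation_histogram(as.integer(names(tab)), as.numeric(tab),
                        voxel_volume_mm3(volume))
}

#' Per-subject densitometry from an attenuation histogram
#'
#' Computes the subject-level CT densitometry statistics:
#' * `tlc_ct_mL` — CT-estimated total lung capacity, voxel count times voxel
#'   volume;
#' * `mean_hu`, `sd_hu` — count-weighted mean and population SD (denominator
#'   N) of the attenuation values;
#' * `lat_hu = mean - 1 SD`, `hat_hu = mean + 1 SD` — the subject-specific
#'   low and high attenuation thresholds;
#' * `pct_low`, `pct_high` — percent of TLC_CT in bins strictly below the
#'   low threshold / strictly above the high threshold (boundary bins count
#'   as neither; thresholds are real-valued while bins are integer HU);
#' * `min_hu`, `max_hu` — observed extremes.
#'
#' @param hist an [attenuation_histogram()].
#' @return Object of class `densitometry_result`.
#' @export
compute_densitometry <- function(hist) {
  stopifnot(inherits(hist, "attenuation_histogram"))
  n <- sum(hist$counts)
  if (n <= 0) stop_pedct("histogram has zero total count", "pedct_bad_histogram")
  v <- as.numeric(hist$bin_values)
  w <- hist$counts / n
  m <- sum(w * v)
  s <- sqrt(sum(w * (v - m)^2))
  lat <- m - s
  hat <- m + s
  structure(list(
    tlc_ct_mL = n * hist$voxel_volume_mm3 / 1000,
    mean_hu = m, sd_hu = s, lat_hu = lat, hat_hu = hat,
    pct_low = 100 * sum(hist$counts[v < lat]) / n,
    pct_high = 100 * sum(hist$counts[v > hat]) / n,
    min_hu = min(hist$bin_values), max_hu = max(hist$bin_values)),
    class = "densitometry_result")
}

#' @export
print.densitometry_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<densitometry_result>\n",
    "  TLC_CT %.1f mL; attenuation mean %.1f HU, SD %.1f HU ",
    "(range %d to %d)\n",
    "  thresholds: low %.1f HU, high %.1f HU\n",
    "  %%TLC_CT below low threshold %.2f%%, above high threshold %.2f%%\n"),
    x$tlc_ct_mL, x$mean_hu, x$sd_hu, x$min_hu, x$max_hu,
    x$lat_hu, x$hat_hu, x$pct_low, x$pct_high))
  invisible(x)
}

#' Densitometry straight from a masked volume
#'
#' Composition of [build_histogram()] and [compute_densitometry()]; because
#' HU are integers, the histogram path is exactly equivalent to computing
#' the moments over the raw masked voxels.
#'
#' @inheritParams build_histogram
#' @return A `densitometry_result`.
#' @export
densitometry_from_volume <- function(volume, mask) {
  compute_densitometry(build_histogram(volume, mask))
}

#' Round a densitometry result for reporting
#'
#' Presentation precision: 0.1 HU for attenuation statistics and
#' thresholds, 0.1 mL for volume, 0.01 for percentages. Internal values stay
#' at full precision; use this only at the reporting boundary.
#'
#' @param x a `densitometry_result`.
#' @return A list with the same fields, rounded.
#' @export
format_densitometry <- function(x) {
  stopifnot(inherits(x, "densitometry_result"))
  list(tlc_ct_mL = round_half_away(x$tlc_ct_mL, 1),
       mean_hu = round_half_away(x$mean_hu, 1),
       sd_hu = round_half_away(x$sd_hu, 1),
       lat_hu = round_half_away(x$lat_hu, 1),
       hat_hu = round_half_away(x$hat_hu, 1),
       pct_low = round_half_away(x$pct_low, 2),
       pct_high = round_half_away(x$pct_high, 2),
       min_hu = x$min_hu, max_hu = x$max_hu)
}

#' Histogram CSV I/O
#'
#' Histograms are exchanged as a two-column CSV (`hu,count`) preceded by a
#' comment header line carrying the voxel volume:
#' `# voxel_volume_mm3=<value>`.
#'
#' @param hist an [attenuation_histogram()].
#' @param path CSV file path.
#' @return `write_histogram_csv` returns `path` invisibly;
#'   `read_histogram_csv` returns an [attenuation_histogram()].
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "attenuation_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# voxel_volume_mm3=%.17g", hist$voxel_volume_mm3), con)
  writeLines("hu,count", con)
  writeLines(sprintf("%d,%.17g", hist$bin_values, hist$counts), con)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  first <- readLines(path, n = 1L)
  vv <- as.numeric(sub("^#\\s*voxel_volume_mm3=", "", first))
  if (is.na(vv))
    stop_pedct("missing '# voxel_volume_mm3=' header line",
               "pedct_bad_histogram")
  df <- read.csv(path, comment.char = "#")
  attenuation_histogram(df$hu, df$count, vv)
}
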