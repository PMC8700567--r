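#' Synthetic cohort specification
#'
#' Describes a synthetic pediatric reference cohort: per-subject ages and the
#' densitometry metrics implied by a reference equation set, plus independent
#' Gaussian measurement noise. Defaults emulate a reference study design of
#' 80 inspiratory chest CTs in children aged 6-17 with roughly equal numbers
#' per year of age.
#'
#' The default noise SDs are calibrated so that refitting the generating
#' models on a large synthetic cohort reproduces the reference equations'
#' coefficients of determination (residual SD = signal SD times
#' `sqrt((1 - r2) / r2)`, with signal SD taken over uniform integer ages
#' 6-17): about 920 mL around the TLC-age line (r2 = 0.59), about 40 HU
#' around the attenuation curves (r2 = 0.42-0.50), and about 0.9 percentage
#' points around the percent-volume curves (r2 ~ 0.5).
#'
#' @param n_subjects number of subjects, >= 2.
#' @param age_min,age_max integer age range in years, `6 <= age_min <= age_max`.
#' @param seed integer seed used by [generate_cohort()].
#' @param reference_set identifier of the equation set used as ground truth;
#'   only `"builtin"` is defined.
#' @param noise_sd_attenuation SD of the noise added to mean attenuation and
#'   to each threshold (HU).
#' @param noise_sd_tlc SD of the noise added to TLC_CT (mL).
#' @param noise_sd_pct SD of the noise added to the percent-volume metrics
#'   (percentage points).
#' @param age_assignment `"uniform"` draws each subject's age uniformly over
#'   the integer range; `"cycle"` assigns ages in rotation
#'   (age_min, age_min+1, ..., age_max, age_min, ...), giving balanced groups.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 80, age_min = 6, age_max = 17,
                        seed = 1, reference_set = "builtin",
                        noise_sd_attenuation = 40, noise_sd_tlc = 920,
                        noise_sd_pct = 0.9,
                        age_assignment = c("uniform", "cycle")) {
  if (n_subjects < 2) stop_pedct("n_subjects must be >= 2", "pedct_bad_spec")
  if (!(6 <= age_min && age_min <= age_max))
    stop_pedct("need 6 <= age_min <= age_max", "pedct_bad_spec")
  if (noise_sd_attenuation < 0 || noise_sd_tlc < 0 || noise_sd_pct < 0)
    stop_pedct("noise SDs must be >= 0", "pedct_bad_spec")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_min = as.integer(age_min), age_max = as.integer(age_max),
                 seed = as.integer(seed), reference_set = reference_set,
                 noise_sd_attenuation = noise_sd_attenuation,
                 noise_sd_tlc = noise_sd_tlc, noise_sd_pct = noise_sd_pct,
                 age_assignment = match.arg(age_assignment)),
            class = "cohort_spec")
}

# Physiologic floors applied after noise: TLC_CT cannot fall below a minimal
# aerated volume and percent fractions cannot be negative.
.min_tlc_ml <- 300
.min_pct <- 0.01

#' Generate a synthetic reference cohort
#'
#' Draws integer ages, evaluates the reference equations at each age --
#' TLC_CT (linear in age), mean attenuation, low/high attenuation thresholds
#' and percent high-attenuation volume (inverse in age), percent
#' low-attenuation volume (inverse in the subject's realized TLC_CT) -- and
#' adds independent Gaussian noise with the spec's SDs. With all noise SDs
#' zero the records lie exactly on the reference curves. The per-subject SD
#' is reported as half the threshold gap, `(hat - lat) / 2`; thresholds are
#' clamped to keep `lat <= mean <= hat` (the clamp binds with negligible
#' probability at the default noise level).
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with one row per subject and columns `subject_id`,
#'   `age_years`, `tlc_ct_ml`, `mean_hu`, `sd_hu`, `lat_hu`, `hat_hu`,
#'   `pct_low`, `pct_high`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 12, age_assignment = "cycle",
#'   noise_sd_attenuation = 0, noise_sd_tlc = 0, noise_sd_pct = 0))
#' coh$mean_hu[coh$age_years == 6]   # -699.4
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!identical(spec$reference_set, "builtin"))
    stop_pedct(paste0("unknown reference_set '", spec$reference_set, "'"),
               "pedct_unknown_reference_set")
  eqs <- reference_set()
  n <- spec$n_subjects
  withr::with_seed(spec$seed, {
    age_range <- seq.int(spec$age_min, spec$age_max)
    ages <- if (spec$age_assignment == "uniform") {
      # index into the vector: sample(x, ...) on a length-1 x would sample 1:x
      age_range[sample.int(length(age_range), n, replace = TRUE)]
    } else {
      rep_len(age_range, n)
    }
    tlc <- pmax(.min_tlc_ml,
                predict(eqs[["tlc_ct_ml~age_years"]], ages) +
                  rnorm(n, 0, spec$noise_sd_tlc))
    mean_hu <- predict(eqs[["mean_hu~age_years"]], ages) +
      rnorm(n, 0, spec$noise_sd_attenuation)
    lat <- predict(eqs[["lat_hu~age_years"]], ages) +
      rnorm(n, 0, spec$noise_sd_attenuation)
    hat <- predict(eqs[["hat_hu~age_years"]], ages) +
      rnorm(n, 0, spec$noise_sd_attenuation)
    lat <- pmin(lat, mean_hu)
    hat <- pmax(hat, mean_hu)
    pct_low <- pmax(.min_pct,
                    predict(eqs[["pct_low~tlc_ct_ml"]], tlc) +
                      rnorm(n, 0, spec$noise_sd_pct))
    pct_high <- pmax(.min_pct,
                     predict(eqs[["pct_high~age_years"]], ages) +
                       rnorm(n, 0, spec$noise_sd_pct))
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               age_years = as.integer(ages),
               tlc_ct_ml = tlc, mean_hu = mean_hu,
               sd_hu = (hat - lat) / 2,
               lat_hu = lat, hat_hu = hat,
               pct_low = pct_low, pct_high = pct_high)
  })
}

cohort_columns <- c("subject_id", "age_years", "tlc_ct_ml", "mean_hu",
                    "sd_hu", "lat_hu", "hat_hu", "pct_low", "pct_high")

#' Cohort CSV I/O
#'
#' Cohort tables are exchanged as plain CSV with the fixed column schema
#' `subject_id, age_years, tlc_ct_ml, mean_hu, sd_hu, lat_hu, hat_hu,
#' pct_low, pct_high`.
#'
#' @param records cohort `data.frame` as produced by [generate_cohort()].
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the validated `data.frame`.
#' @export
write_cohort_csv <- function(records, path) {
  check_cohort(records)
  write.csv(records[cohort_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_cohort(df)
  df
}

check_cohort <- function(records) {
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols))
    stop_pedct(paste("cohort table lacks columns:",
                     paste(missing_cols, collapse = ", ")),
               "pedct_bad_cohort")
  if (nrow(records) == 0)
    stop_pedct("cohort table is empty", "pedct_bad_cohort")
  if (any(records$tlc_ct_ml <= 0))
    stop_pedct("tlc_ct_ml must be positive", "pedct_bad_cohort")
  bad <- records$lat_hu > records$mean_hu | records$mean_hu > records$hat_hu
  if (any(bad))
    stop_pedct("need lat_hu <= mean_hu <= hat_hu for every record",
               "pedct_bad_cohort")
  invisible(TRUE)
}
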