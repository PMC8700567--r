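#' Five-number summaries of densitometry metrics by age group
#'
#' Splits the cohort into one group per integer year of age present and
#' reports `median (p25, p75) (min, max)` for each requested metric, the
#' layout used for pediatric reference tables. Percentiles use linear
#' interpolation between order statistics (`quantile()` type 7); with the
#' typical 6-8 subjects per age group the convention matters and is
#' therefore fixed.
#'
#' @param records cohort `data.frame` (see [generate_cohort()]).
#' @param metrics character vector of numeric columns to summarize.
#' @return A long-format `data.frame` with columns `group_label`, `metric`,
#'   `n`, `median`, `p25`, `p75`, `min`, `max`; one row per group x metric,
#'   groups in increasing age order.
#' @export
summarize_by_age <- function(records,
                             metrics = c("mean_hu", "lat_hu", "hat_hu",
                                         "pct_low", "pct_high")) {
  check_cohort(records)
  ages <- sort(unique(records$age_years))
  groups <- lapply(ages, function(a) records[records$age_years == a, ])
  labels <- sprintf("%d-year-old", ages)
  summarize_groups(groups, labels, metrics)
}

# Bin edges reproduce the reference-table layout: the first bin runs from
# the observed minimum to 1500 mL (closed), then half-open width-500 bins
# (1500, 2000], (2000, 2500], ... out to the observed maximum.
tlc_bin_breaks <- function(tlc) {
  lo <- min(tlc)
  hi <- max(tlc)
  upper <- seq(1500, max(1500, 500 * ceiling(hi / 500)), by = 500)
  c(lo, upper[upper >= lo])
}

#' Five-number summaries of percent-volume metrics by TLC_CT bin
#'
#' Groups subjects by CT lung volume: a first bin from the data minimum to
#' 1500 mL (inclusive), then half-open 500 mL bins `(1500, 2000]`,
#' `(2000, 2500]`, and so on. Empty bins are omitted. Summary layout as in
#' [summarize_by_age()].
#'
#' @inheritParams summarize_by_age
#' @return Long-format `data.frame` as in [summarize_by_age()], with
#'   `group_label` like `"897.3-1500"` or `"1501-2000"`.
#' @export
summarize_by_tlc_bin <- function(records,
                                 metrics = c("pct_low", "pct_high")) {
  check_cohort(records)
  tlc <- records$tlc_ct_ml
  breaks <- tlc_bin_breaks(tlc)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + 500)
  idx <- cut(tlc, breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  labels <- vapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- if (i == 1) format(breaks[1]) else format(breaks[i] + 1)
    paste0(lo, "-", format(breaks[i + 1]))
  }, character(1))
  present <- sort(unique(idx))
  groups <- lapply(present, function(i) records[idx == i, ])
  summarize_groups(groups, labels[present], metrics)
}

summarize_groups <- function(groups, labels, metrics) {
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    do.call(rbind, lapply(metrics, function(m) {
      v <- g[[m]]
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(group_label = labels[i], metric = m, n = nrow(g),
                 median = q[2], p25 = q[1], p75 = q[3],
                 min = min(v), max = max(v))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-cohort headline medians
#'
#' Median (minimum, maximum) of TLC_CT and of mean lung attenuation over the
#' whole cohort, the two headline numbers of a reference-cohort report.
#'
#' @param records cohort `data.frame`.
#' @return Named list: `tlc_ct_ml` and `mean_hu`, each `c(median, min, max)`.
#' @export
cohort_medians <- function(records) {
  check_cohort(records)
  five <- function(v) c(median = median(v), min = min(v), max = max(v))
  list(tlc_ct_ml = five(records$tlc_ct_ml),
       mean_hu = five(records$mean_hu))
}

#' Render a group summary as a Markdown table
#'
#' Cells follow the reference-table format `median (p25, p75) (min, max)`,
#' with 0.1 precision for HU and mL metrics and 0.01 for percentages.
#'
#' @param summary long-format `data.frame` from [summarize_by_age()] or
#'   [summarize_by_tlc_bin()].
#' @return Character vector of Markdown lines.
#' @export
format_summary_markdown <- function(summary) {
  fmt_cell <- function(r) {
    digits <- if (grepl("^pct", r$metric)) 2 else 1
    f <- function(v) formatC(round_half_away(v, digits),
                             format = "f", digits = digits)
    sprintf("%s (%s, %s) (%s, %s)", f(r$median), f(r$p25), f(r$p75),
            f(r$min), f(r$max))
  }
  metrics <- unique(summary$metric)
  groups <- unique(summary$group_label)
  header <- paste0("| Group | n | ", paste(metrics, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(metrics) + 2), collapse = "|"),
                "|")
  body <- vapply(groups, function(g) {
    sub <- summary[summary$group_label == g, ]
    cells <- vapply(metrics, function(m) {
      r <- sub[sub$metric == m, ]
      if (nrow(r) == 0) "" else fmt_cell(r[1, ])
    }, character(1))
    paste0("| ", g, " | ", sub$n[1], " | ",
           paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, sep, unname(body))
}
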