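---
title: "Pediatric CT lung densitometry: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pediatric CT lung densitometry: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedlungct)
```

## The problem

Quantitative chest CT grades obstructive and parenchymal lung disease by the
distribution of voxel attenuation (Hounsfield units, HU) inside the lungs.
In adults, fixed cutoffs are standard: voxels below −950 HU at full
inspiration count as emphysema-like hyperinflation. In children this breaks
down, because normal lung attenuation itself changes with age as the air
fraction of the parenchyma grows. A workable pediatric alternative defines
*subject-specific* thresholds from each child's own attenuation histogram:

* **LAT** (low attenuation threshold) = mean − 1 SD,
* **HAT** (high attenuation threshold) = mean + 1 SD,

with `%TLC_CT` low/high = the percent of the CT-measured lung volume
(`TLC_CT`, a total lung capacity estimate from voxel counting) strictly
below LAT or strictly above HAT. Age-specific reference equations for these
quantities then play the role that spirometry reference equations play for
lung function.

This package implements the full pipeline — segmentation, histogram
densitometry, reference-model fitting, cohort summaries — plus a synthetic
phantom/cohort generator, because the original imaging data behind the
reference equations are not public and everything must be validatable
without them.

## Per-subject statistics

For a masked volume the histogram has one width-1 bin per observed integer
HU. Mean and SD are count-weighted moments; the SD uses the population
convention (denominator N) — at 10^5–10^6 voxels the N vs N−1 distinction
is far below reporting precision, but one convention has to be fixed for
reproducibility. Thresholds are real-valued; a bin contributes to `pct_low`
only when its integer value is strictly below LAT, and to `pct_high` only
strictly above HAT, so voxels in boundary bins count as neither (the
source's "<"/">" notation, exercised by a constructed two-bin histogram
whose bins fall exactly on mean ± 1 SD). Reported values are rounded to
0.1 HU and 0.01 percentage points only at the formatting boundary.

## Reference models

`TLC_CT` versus age is linear, `a + b·x`; attenuation metrics versus age or
`TLC_CT` follow the inverse (hyperbola) form `a + b/x`, which captures the
fast early decline and the asymptote `a` toward adolescence. The inverse
model is fit by ordinary least squares on the transformed predictor `1/x`:
for this family the transformed-predictor OLS solution *is* the
least-squares hyperbola, and r² computed on the original response scale
equals the transformed-scale value, so nonlinear least squares would add
nothing but iteration. Coefficient standard errors come from
`σ²(XᵀX)⁻¹` evaluated directly, which stays silent (SE = 0) on perfect
fits. Spearman correlations use average ranks for ties and the two-sided
t approximation for p; exact permutation p-values are out of scope since
the reference report only states thresholds such as p < 0.0001.

The stored equation set (seven equations, r² 0.42–0.76, n = 80, ages 6–17)
ships as a versioned JSON resource and is the default both for prediction
and as ground truth for the cohort generator. Ages enter as integer years,
matching the year-of-age group design of the reference cohort.

## The parenchymal attenuation model

Empirically, pediatric inspiratory lung histograms are strongly asymmetric
around the one-SD thresholds: the fraction below mean − 1 SD is roughly
0.2–8%, far below the 15.87% a Gaussian would give, while the fraction
above mean + 1 SD sits near 8–15%. The smallest model that can hit all
four targets (mean, SD, both tail fractions) is a two-component mixture:

$$f(x) = (1-w)\,\mathcal{N}(x;\mu,\sigma^2) +
         \frac{w}{s}\,e^{-(x-\mu)/s}\,\mathbf{1}[x \ge \mu]$$

a narrow Gaussian bulk of aerated parenchyma plus a shifted-exponential
tail of denser voxels (vessels, airway walls, juxta-mediastinal lung)
starting at the bulk mean with scale `s` toward higher HU. The dense tail
inflates the overall SD, which pushes `mean − 1 SD` deep below the narrow
bulk — exactly the observed asymmetry. Calibration is deterministic: given
`(w, s)`, the bulk parameters follow in closed form from moment matching
(`μ = m − ws`, `σ² = (V − w s²(2−w))/(1−w)`), and the remaining two
tail-fraction equations are solved by Nelder–Mead over `(logit(2w), log s)`
from several fixed starts. Tolerances: 0.5 HU on mean/SD (exact up to
floating point, by construction), 0.3 percentage points on each fraction;
non-convergence raises a calibration-infeasible error naming the worse
target. With symmetric Gaussian targets (15.8655% both sides) the solver
collapses to `w ≈ 0`, the pure-normal limit.

```{r calibration}
d <- calibrate_distribution(-803, 147.3, 0.0053, 0.1020)  # 10-year-old medians
d
```

Sampled voxels are rounded to integer HU half-away-from-zero (the CT
storage convention) and clamped to [−1024, 3071]. Rounding adds ~1/12 HU²
of variance and can shift an empirical tail fraction by up to the local
density times one bin width (~0.05 percentage points here); Monte-Carlo
tests therefore allow 3 standard errors plus a 0.1-point discretisation
margin.

## What the phantom emulates — and what it does not

A phantom is a soft-tissue elliptical cylinder (default 40 HU) spanning the
full z extent of a 96³ grid at 2 mm isotropic spacing (desk-scale default;
configurable), surrounded laterally by exterior air (−1000 HU), containing
two lung ellipsoids filled with i.i.d. draws from the calibrated mixture,
plus optional extra air pockets. This reproduces the *statistical* structure
the analysis rests on — HU distributions, volumes, exterior air topology —
but none of the things a scanner produces: no spatially correlated noise
texture, no reconstruction-kernel effects, no anatomy (airway tree, fissures,
gravity-dependent gradients), no breathing variability. A green pipeline
test therefore establishes algorithmic correctness on the stated model, not
clinical performance on real scans.

The cohort generator draws integer ages (uniform by default; a balanced
"cycle" mode mirrors the equal-groups design), evaluates the stored
equations, and adds independent Gaussian noise. The noise SDs are derived
once from the published r² values — residual SD = signal SD ×
√((1−r²)/r²) with signal SD taken over uniform ages 6–17 — giving defaults
of 920 mL (TLC, r² = 0.59), 40 HU (attenuation curves, r² = 0.42–0.50) and
0.9 points (percent metrics, r² ≈ 0.49). Physiologic floors (TLC ≥ 300 mL,
percents ≥ 0.01) and the clamp keeping `lat ≤ mean ≤ hat` bind with
negligible probability at these levels but keep every record valid. `%low`
is predicted from the subject's realized TLC (its published predictor);
`%high` from age. With all noise SDs zero, records lie exactly on the
curves.

## Segmentation conventions

The interactive workflow this replaces sets an attenuation window visually
and erases exterior air by hand. Here: window = [−1024, −200] HU by default
(no published bounds exist; this brackets aerated lung and airway air while
excluding soft tissue at ≥ −100 HU), then 6-connected components of the
candidate mask are filtered. A component is discarded if it touches a
lateral (x or y) grid face — exterior air; the z faces are exempt because
cranial/caudal slices may legitimately truncate lung — or if it is smaller
than 5 mL (stray pockets; a real gastric bubble either connects to exterior
air or falls under this floor). Central airways stay inside the mask, as in
the source workflow where their share is under 2% of the volume. The
lateral-face rule is a convention of this implementation, not a claim about
the original manual procedure. About 1% of calibrated lung voxels exceed
−200 HU (the dense tail) and are excluded by the window; the 2% pipeline
volume tolerance absorbs this by design rather than by tuning.

## Numerical and formatting choices

* Percentiles in group summaries: linear interpolation between order
  statistics (`quantile` type 7), fixed because P25/P75 of 6–8-subject
  groups depend visibly on the convention.
* TLC bins: first bin [data minimum, 1500 mL] closed, then half-open
  (1500, 2000], (2000, 2500], …, so boundary membership is deterministic
  (1500.0 falls in the first bin, 1500.5 in the second).
* Rounding of presented predictions: half away from zero, at 1 HU (or 10 HU
  where reference values are quoted to tens).
* Seeds are explicit arguments everywhere; generators snapshot and restore
  the caller's RNG state (`withr::with_seed`), so no global state leaks.

## Known limitations

Real CT data are absent by construction: published empirical r², Spearman
correlations and group medians appear only as stored constants and
calibration targets, never as quantities this package claims to reproduce.
The acceptance checks cover the deterministic predicted values of the
stored equations and the self-consistency of the synthetic world
(calibration, recovery, segmentation accuracy). The 2-SE fit-recovery check
is asserted across ten fixed seeds (≥ 8 must pass) because a single cohort
satisfies a 2-SE criterion only with ~95% probability even under perfect
calibration. NIfTI support is deliberately minimal (little-endian,
single-file, 3D scalar images) — enough for interchange with standard
neuroimaging/medical-imaging tools, not a general reader.
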