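Package: pedlungct
Title: Pediatric Quantitative Chest CT Lung Densitometry
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Quantitative chest computed tomography (CT) densitometry for
    pediatric lungs. Segments the lung-plus-central-airway voxel set from a
    Hounsfield-unit attenuation volume, computes per-subject attenuation
    histogram statistics (CT-estimated total lung capacity, mean and standard
    deviation of attenuation, subject-specific low and high attenuation
    thresholds at mean -/+ 1 SD, and the percent lung volume below or above
    them), fits age- and volume-dependent reference equations (linear and
    inverse/hyperbola forms) with Spearman correlations, and produces cohort
    summary tables. Includes a synthetic phantom and cohort generator with a
    calibrated non-Gaussian parenchymal attenuation model so that the whole
    pipeline is testable without access to patient imaging data, plus minimal
    NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
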