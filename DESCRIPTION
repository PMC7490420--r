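Package: predimr
Title: Two-Sample Mendelian Randomization and Meta-Analysis for Glycaemic
    Exposures and Vascular Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether nondiabetic glycaemic variation
    (prediabetes) causally affects vascular outcomes, combining two
    complementary arms.  The genetic arm builds "exposure-only" instruments
    from GWAS summary statistics (genome-wide significance filtering,
    exclusion of disease-associated variants, greedy LD clumping, and
    exposure-outcome harmonization with palindromic-variant handling) and
    estimates causal effects by inverse-variance weighting, MR-Egger and the
    weighted median, each with robust variants, plus simulation-based
    pleiotropy/outlier detection with a distortion test (MR-PRESSO style)
    and leave-one-out diagnostics.  The observational arm pools study-level
    risk estimates with the DerSimonian-Laird random-effects model and
    provides heterogeneity, subgroup, leave-one-study-out and
    publication-bias (Begg, Egger) analyses.  Seeded synthetic-data
    generators emit every input the pipeline consumes with ground truth
    attached, so both arms are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
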