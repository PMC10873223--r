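Package: collateralmap
Title: Phase-Resolved Collateral Perfusion Maps from Dynamic
    Contrast-Enhanced MR Angiography in Acute Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and analyses phase-resolved collateral perfusion
    maps ("collateral maps") from 4D dynamic contrast-enhanced MR
    angiography time series in acute anterior-circulation ischemic
    stroke.  The pipeline extracts arterial and venous signal
    intensity-time curves, divides the acquisition into arterial,
    capillary, early venous, late venous and delay phases, delineates
    nested hypoperfusion masks by mirrored-hemisphere comparison, grades
    collateral perfusion on a six-level scale over the eight ASPECTS
    regions of the middle cerebral artery territory, and computes
    patient-level predictors of lesion growth (Tmax/DWI ratio, precise
    and approximate collateral ratios).  Evaluation statistics include
    exact binomial diagnostic performance, Lin's concordance correlation
    with BCa bootstrap differences, Firth penalized logistic regression,
    McNemar and DeLong tests, and Cohen's weighted kappa.  A seeded 4D
    digital perfusion phantom with known ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    boot,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
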