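Package: igri
Title: Integrated Glaucoma Risk Index from Visual Field, OCT and IOP Examinations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes a continuous 0-1 glaucoma severity score (the integrated
    glaucoma risk index, I-GRI) from six routine examination features: pattern
    standard deviation (PSD) and mean deviation (MD) from the visual field test,
    superior/inferior/temporal retinal nerve fiber layer thickness (RNFL_S,
    RNFL_I, RNFL_T) from optical coherence tomography, and intraocular pressure
    (IOP). Features are min-max normalized to a severity-aligned unit scale,
    augmented with a k-nearest-neighbor class-fraction feature (NNI) computed
    against a labeled reference cohort, and combined by an importance-weighted
    sum. Includes recalibration tools (gradient-boosted-tree feature importance,
    decision-threshold derivation, base:NNI ratio sweep), MD-based severity
    staging, a synthetic two-class cohort generator standing in for protected
    clinical data, evaluation utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    FNN
Config/testthat/edition: 3
RoxygenNote: 7.3.3
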