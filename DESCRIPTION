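Package: ctiq
Title: CT Image Quality Metrics and Dose-Reduction Analysis on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates replicate synthetic CT phantom slices (Catphan 600-style
    sensitometry, low-contrast and resolution modules, plus a simplified abdomen)
    with known Hounsfield-unit ground truth, blur and noise, and evaluates image
    quality the way phantom dose-reduction studies do: ROI noise as the mean of
    region standard deviations, contrast-to-noise ratio, insert HU accuracy,
    edge-method modulation transfer function, and fold-improvement relative to
    filtered back-projection. Condition means, contrasts against a reference
    scan condition and Dunnett-adjusted p-values reproduce the statistical
    reporting layout used for reconstruction-algorithm comparisons across
    dose and pitch grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
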