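Package: fnirsbci
Title: Feature-Combination Selection for fNIRS Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class classification of functional near-infrared
    spectroscopy (fNIRS) signals in brain-computer interface applications.
    Converts two-wavelength optical-density recordings to oxygenated and
    deoxygenated hemoglobin concentration changes via the modified
    Beer-Lambert law, removes physiological noise with zero-phase band-reject
    filtering and polynomial detrending, extracts six per-epoch features
    (mean, slope, variance, peak, skewness, kurtosis), and searches all 2-
    and 3-feature combinations with a from-scratch linear discriminant
    analysis classifier under repeated stratified k-fold cross-validation.
    Includes an exact paired sign-flip permutation test for comparing
    feature combinations, a synthetic-recording generator emulating a
    block-design mental-arithmetic paradigm, and packaged reference accuracy
    tables from a seven-subject mental-arithmetic study for reproducing
    cross-subject summary results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
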