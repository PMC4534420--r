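Package: aslpower
Title: Voxel-Wise Time-to-Significance Analysis for White-Matter ASL
    Perfusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how long a background-suppressed PCASL
    acquisition must average before white-matter voxels show a
    statistically significant perfusion signal.  Provides a synthetic
    generator for interleaved label/control ASL series with a
    co-registered single-inversion-recovery volume, cumulative paired
    t-statistics over signal-average prefixes, significant-fraction and
    time-to-significance maps under uncorrected and Bonferroni
    thresholds, non-responder detection, SIR-based white-matter
    segmentation with periventricular/peripheral/deep sub-masks,
    t-histogram evolution, and asymptotic response-curve fitting
    (exponential recovery, logarithmic, and Michaelis-Menten fractional
    models, plus the square-root-of-N law for mean t-values).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
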