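Package: lockrtools
Title: Thermodynamic Tuning and Quantitative Readout Analysis for LOCKR
    Protein Switch Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for engineering and quantifying de novo
    designed LOCKR (Latching Orthogonal Cage-Key pRotein) switch biosensors.
    Implements a five-state mass-action equilibrium model of the two-component
    switch (closed, open, target-bound, key-bound false positive, and ternary
    states) with mutation-based tuning of sensor energetics to a target
    concentration window; enumeration of sensing-motif threadings into the
    alpha-helical registers of a latch segment; ratiometric FRET timecourse
    quantification with background subtraction, R/R0 and dataset
    normalizations, signal-to-noise estimation and brightness-based quality
    control; puncta detection with circularity and size filters plus Pearson
    and Manders co-localization coefficients; and Perseus-style processing of
    proximity-labeling proteomics intensity tables (flag filtering, median
    normalization, replicate correlation QC, downshifted-normal imputation,
    Welch differential enrichment). A synthetic-data module generates every
    input with known ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    Biostrings,
    limma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
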