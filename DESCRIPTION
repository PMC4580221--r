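Package: hicnoise
Title: Random-Ligation Noise, Bias and Structure Analysis for Hi-C Di-Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify spurious (random) proximity-ligation noise in
    Hi-C libraries and its downstream consequences. Implements di-tag
    classification and library-level QC summaries, the expected hybrid di-tag
    fraction in species-mixing experiments under a random-ligation model,
    powerlaw distance-decay curves, maximum-likelihood estimation of 20x20
    fragment-length and GC-content bias matrices from trans-chromosomal data,
    iterative coverage correction (matrix balancing) and distance correction
    of binned contact matrices, A/B compartment calling from interaction-profile
    correlation eigenvectors, reproducibility statistics (distance-stratified
    Spearman correlation and the deviation-from-expected-slope, DES), and
    directionality-index TAD boundary detection with consensus sets and
    aggregate boundary profiles. Includes a synthetic di-tag generator with
    known ground truth (distance decay, planted TADs and compartments,
    injected biases, species mixtures and a tunable random-ligation fraction)
    used to exercise the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
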