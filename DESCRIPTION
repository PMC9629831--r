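Package: moltmap
Title: Spatiotemporal Mapping of the Oscillating Pharyngeal Cuticle Secretome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a phase-resolved map of genes that oscillate with
    the Caenorhabditis elegans molting cycle and characterises the proteins
    they encode. Provides harmonic-regression phase fitting and hourly
    binning of time-course expression, overlay of molt-upregulated gene
    sets, tissue-enrichment and secretome classification from single-cell
    expression summaries and signal-peptide scores, native SEG
    low-complexity detection, intrinsically disordered region
    quantification, transcript-weighted temporal property profiles,
    pairwise-identity family discovery with consensus frequency matrices,
    and a synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
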