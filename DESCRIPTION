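Package: cospectra
Title: Non-Semantic Labelling of Sequence Data via Self-Information
    Spectra and Co-Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Entropy-reducing representation operators (mean, standard
    deviation, rank, bin centre, bin frequency, self-information)
    tensorially combined with panels of probability, ordering and binning
    models, mapping both data elements and models into dual metric spaces
    of spectra and co-spectra.  Front-ends turn sequence files into k-mer
    zipfian rank/self-information co-spectra with turning-point and
    adapter-contamination diagnostics, alignment hit tables into
    windowed-depth self-information spectra across reference panels, and
    taxonomy hit-count tables into batch co-spectra for sequencing-centre
    quality control.  Bespoke distances (rank-weighted zipfian,
    cluster-projection), classical multidimensional scaling, hierarchical
    heatmap ordering with Newick dendrograms, and a fully seeded synthetic
    data generator are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
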