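Package: ms2sim
Title: Transformer-Based Spectral Similarity and Explanation for Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts structural (Tanimoto-style) similarity between tandem
    mass spectrometry (MS/MS) spectra from mass-difference matrices of
    product ions and neutral losses, using a two-tower transformer
    regression model trained on structure-labelled spectral libraries.
    Includes MGF/MSP readers and the standard peak preprocessing pipeline,
    the mass-difference-matrix / aligned-matrix encoding, model training
    with balanced Tanimoto-bin pair sampling, spectral library search,
    classical cosine baselines, an evaluation battery (precision-recall at
    structural-similarity cut-offs, per-bin squared error, Pearson
    correlation), molecular-network edge export, and a post-hoc
    attention-relevance explanation that maps a predicted score back to
    query-reference fragment pairs. A synthetic spectra generator with
    exactly known ground-truth similarity supports end-to-end testing
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
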