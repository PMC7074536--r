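Package: holonet
Title: Molecular Networking and Multi-Omic Mining of Sponge Holobionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating glycosylated natural products in tandem
    mass spectrometry data from marine sponge holobionts. Implements
    classical and feature-based molecular networking (modified cosine
    scoring, consensus clustering, mutual top-K topology), declarative
    substructure-motif detection and propagation, glycosidic neutral-loss
    classification, delta-mass congener annotation, congener abundance and
    feature-overlap quantification, microbiome diversity summaries, and
    co-occurrence screening of metagenome bins for joint
    sterol-biosynthesis and glycosyltransferase capacity. Ships a
    synthetic-data engine that emulates glycoside fragmentation spectra,
    multi-sample LC/MS feature tables, amplicon community profiles, and
    annotated metagenome bins with known ground truth, so the whole
    pipeline is exercisable end to end without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
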