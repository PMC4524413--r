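Package: lcmspipe
Title: Stepwise LC-MS Metabolomics Processing with a Typed Stage Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Modular processing of liquid chromatography-mass spectrometry
    (LC-MS) metabolomics data: mzML ingestion, wavelet-based centroiding of
    profile spectra, noise filtering and baseline correction, ion-trace
    (feature) extraction, chromatographic deconvolution, grouping of
    co-eluting features into compound spectra, isotope and adduct
    annotation, reference-library identification, retention-time alignment,
    and assembly of a cross-sample feature matrix.  Processing steps are
    pure functions over a small hierarchy of typed containers (scan,
    feature, feature set) and can be chained in a validated, snapshotting
    stage-graph executor.  A synthetic-data generator produces ground-truth
    mzML runs of known compounds so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    jsonlite,
    signal,
    Matrix,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
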