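Package: epimosaic
Title: Epileptiform Activity, Pathological-Cell Topography and Treatment
    Response Analysis for Mosaic Cortical Malformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain linking electrophysiological hyperexcitability in
    acute cortical slices to the topography of pathological (mTOR-hyperactive,
    senescent) cells and to longitudinal treatment response. Detects
    interictal-like discharges (IILDs) and multi-unit activity (MUA) on
    multi-electrode-array recordings via a filter-square-normalize-threshold
    procedure, classifies electrodes by activity type, registers the electrode
    grid onto histology images with landmark-based affine transforms and
    quantifies dysmorphic-neuron density per activity class, segments and
    counts marker-positive cells in histology images with co-labeling
    statistics, detects electrographic seizures on EEG via Morlet
    time-frequency power and compares treatment phases, and provides exact
    small-sample two-tailed Mann-Whitney statistics. A seeded synthetic-data
    generator emulates recordings, cell maps, images and seizure timelines
    with known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    EBImage,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    withr
Config/testthat/edition: 3
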