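Package: HTFISH
Title: High-Throughput DNA/RNA FISH Image Analysis with Allele-Level
    Transcription Calling and Radial Nuclear Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput combined DNA/RNA
    fluorescence in situ hybridization (FISH) imaging in 384-well plates.
    Provides a seeded synthetic microscopy-image generator with ground
    truth, cross-correlation registration of sequential acquisition
    rounds, DAPI-based nucleus segmentation with size/circularity quality
    control, Laplacian-of-Gaussian FISH spot detection with sub-pixel
    localization, allele-level active/inactive/no-transcription
    classification from DNA-RNA spot distances, and normalized radial
    nuclear positioning via per-nucleus distance transforms, with
    two-sample Kolmogorov-Smirnov comparison of radial distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
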