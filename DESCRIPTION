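Package: tongueCBIR
Title: Content-Based Tongue Image Retrieval with Dominant Color and
    Edge Histogram Descriptors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and ranked retrieval for clinical tongue
    images. Implements a dominant-color descriptor built on a generalized
    Lloyd (LBG) vector quantizer with data-driven HSV-region
    initialization and cluster split/merge refinement, an MPEG-7 style
    edge histogram descriptor extended with global and semiglobal
    histograms, and a normalized weighted fusion of the two descriptor
    distances for content-based retrieval with precision/recall
    evaluation. Includes a seeded synthetic phantom generator emulating
    tongue color and texture classes so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: ImageProcessing, Classification, Software
RoxygenNote: 7.3.3
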