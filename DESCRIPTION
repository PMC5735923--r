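Package: blastoquant
Title: Quantitative Image Analysis of Bovine Blastocyst Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated processing of single-embryo brightfield micrographs of
    bovine blastocysts. Standardizes an input image to an 8-bit greyscale
    640x480 frame, localizes the embryo with a two-stage circular Hough
    transform on a binarized gradient image, partitions it into expanded
    (ER), reduced (RR) and trophectoderm (TE) regions, and extracts 36
    quantitative variables: grey-level co-occurrence texture statistics,
    dark/light inclusion circle counts and intensities, Otsu and first-order
    intensity descriptors, and watershed-based inner-cell-mass shape
    descriptors. Includes embryologist-grade utilities (modal grade,
    Fleiss and Light inter-rater kappa) and a seeded synthetic blastocyst
    phantom generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tools,
    stats,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
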