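Package: foodseg
Title: Automated Segmentation of Multispectral Food Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated, unsupervised segmentation of multispectral
    reflectance cubes of food samples (meat, creams, olives). Implements
    per-band min-max normalization and Standard Normal Variate spectral
    preprocessing, unsupervised spectral band-pair selection by minimizing
    an edge-based contrast measure on band-difference images, 1-D Gaussian
    mixture thresholding with EM and minimum-message-length model selection
    (Bayes-rule threshold for bimodal histograms, skew-directed tail
    rejection for unimodal ones), and a two-stage cascade that first removes
    the background and then fat/connective tissue. Ships a seeded phantom
    generator with ground-truth masks and the matching evaluation toolkit
    (area-fraction regression, binary colocalization, per-band reflectance
    summaries), plus cube/mask I/O for multi-page TIFF and a lossless
    archive format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
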