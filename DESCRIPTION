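Package: pixelfold
Title: Pseudo-Image Folding and CNN Attribution for High-Dimensional Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms high-dimensional numeric tables (for example bulk or
    single-cell gene-expression matrices) into square one-feature-per-pixel
    pseudo-images, trains a 2D convolutional network classifier over repeated
    seeded train/test iterations, and identifies discriminative input features
    by accumulating gradient-based attributions (saliency, integrated
    gradients) over correctly classified held-out samples. Includes a
    needle-in-a-haystack synthetic benchmark generator with planted
    class-conditional features, seeded pixel shuffling, and toy pattern images
    so the full pipeline is testable without external data. The convolutional
    engine (stride-1 im2col convolutions, batch normalisation, adaptive
    average pooling, Adam) is implemented on dense base-R arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
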