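Package: mbcluster
Title: Memory-Bounded Mini-Batch K-Means Clustering for Large Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mini-batch k-means clustering for large observation-by-feature
    matrices such as single-cell expression data. Operates identically on
    in-memory dense, in-memory sparse, and on-disk HDF5 inputs by reading only
    the current mini-batch of rows, so memory use is bounded by the batch size
    rather than the dataset size. Provides k-means++ initialization on a
    subsample, block-wise final label prediction, HDF5 chunk-geometry
    selection and rechunking utilities, within-cluster sum of squares and
    adjusted Rand index evaluation, a Gaussian-mixture synthetic data
    generator with known labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    rhdf5,
    data.table,
    jsonlite,
    optparse,
    generics,
    tibble,
    ggplot2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
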