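Package: apaxis
Title: Anterior-Posterior Axis Reconstruction and Stripe-Gene Mining from Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a one-dimensional anterior-posterior (AP) body axis from
    2-D embeddings of single-nucleus RNA-seq data of segmenting arthropod embryos,
    generates genome-wide smoothed expression profiles along the reconstructed axis,
    and mines the profiles for segmentation-stripe genes. Includes count-matrix I/O
    and QC filtering, a delegated clustering/embedding stage, density-ridge spline
    axis construction with arc-length position assignment, mirrored loess profiling
    at 80 axis subdivisions, two-round hierarchical-clustering gene selection,
    first-derivative and correlation analyses, in-cluster expression randomization
    experiments with quantitative axis-recovery scoring, and a negative-binomial
    germ-band simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    MASS,
    igraph,
    irlba,
    RANN,
    uwot,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
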