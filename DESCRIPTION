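Package: bcs3d
Title: Depth-Image Body Condition Scoring for Dairy Heifers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring body reserves of gestating dairy heifers from
    overhead depth images. Implements the full chain from stereo depth
    acquisition (block matching, triangulation, depth/point-cloud conversion
    and file I/O), through automatic detection of the four pelvic landmarks
    (tops of the ischia, bases of the sacra), landmark-based normalization of
    the dorsal hips-to-pins surface onto a fixed 150 x 150 grid, and a
    PCA-plus-linear-regression shape model predicting body condition score
    (BCS, 0-5 scale), to longitudinal per-animal monitoring with aberrant
    record filtering, LOESS smoothing and method comparison. A synthetic
    dorsal-surface generator with a latent fatness parameter, sensor noise,
    pose jitter and pixel dropout makes every stage testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'bcs3d-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'geometry.R'
    'io-png.R'
    'io-ply.R'
    'landmarks.R'
    'normalize.R'
    'shapemodel.R'
    'quality.R'
    'loess.R'
    'monitor.R'
    'herd-data.R'
    'pipeline.R'
    'cli.R'
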