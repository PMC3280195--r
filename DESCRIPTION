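Package: mtalign
Title: Robust Alignment of Multi-Tag Fluorescence Microscopy Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registration of multi-tag fluorescence/phase-contrast image
    stacks acquired by sequential staining (e.g. toponome imaging). Pairwise
    shifts are estimated by maximizing mutual information over translations
    with a derivative-free pattern search and bicubic sub-pixel
    interpolation, independently on K disjoint subimage blocks; pairwise
    block distances yield an outlier rule and a standard-deviation
    confidence measure. The N-1 pairwise results are completed into
    skew-symmetric shift matrices (a registration graph), and the reference
    image with maximal overlap (RIMO) is selected by minimizing a
    symmetric-difference shift metric, after which the whole stack is
    re-aligned to the RIMO. Includes a seeded synthetic-stack generator
    (uniform sub-pixel drifts with gamma and blur corruption) for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
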