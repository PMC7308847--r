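Package: shadecor
Title: Retrospective Shading Correction for Brightfield Whole-Slide Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Retrospective flat-field (shading) correction for stacks of
    brightfield whole-slide-imaging tiles. Candidate flat fields are built by
    sorting intensities at every pixel across the stack, and the candidate
    with the smoothest appearance - measured as the image-wide sum of the
    local coefficient of variation - is selected per channel. Because no
    smoothness is enforced on the estimate itself, static per-pixel gain
    variation (fixed-pattern noise) is retained in the field and removed by
    the division correction. Includes quantitative evaluation (correction
    score, PSNR, empty-slide reference fields, subset-size convergence), a
    synthetic tile-collection generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
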