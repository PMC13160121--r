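Package: gastrupol
Title: Quantifying Symmetry Breaking in 3D Stem-Cell Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify spatial symmetry breaking in 3D human
    pluripotent stem-cell aggregates (gastruloids). Detects nuclei in
    multichannel image stacks or maximum-intensity projections, calls
    marker-positive cells, estimates the maximal-separation axis between two
    cell populations, builds normalized line-trace profiles, scores
    polarization against a label-permutation null with per-permutation axis
    refitting, classifies aggregates as mixed, hemispherical, radial or
    fragmented, and computes delta-delta-Ct relative expression from qPCR Ct
    tables. Includes a ground-truthed synthetic aggregate generator and
    microscopy-like rasterizer for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    mclust,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
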