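Package: mitocount
Title: Ratiometric Quantification of Mitophagy from Dual-Fluorophore Reporter Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and measures mitolysosomes ("red-only" puncta) in
    two-channel mCherry/GFP fluorescence images of cells or tissue expressing
    a tandem pH-sensitive mitophagy reporter. Builds a pixel-wise mCherry/GFP
    ratio image, finds peaks by topographic prominence (ImageJ "Find Maxima"
    semantics), filters them with an adaptive red-intensity threshold, grows a
    binary mitophagy mask, and reports per-region morphometrics as a CSV
    table. Reads multi-channel TIFF images and ImageJ ROI files (.roi, .zip)
    or label masks; includes a synthetic-image generator with known ground
    truth and a command-line interface with single-image and batch modes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
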