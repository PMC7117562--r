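Package: feulgen
Title: DNA Ploidy Assessment from Feulgen-Stained Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated imaging cytometry for DNA ploidy assessment of
    Feulgen-stained tissue sections. Converts brightfield intensities to
    optical density, integrates optical density over operator-delineated
    nuclei (IOD), normalizes epithelial IODs to the modal IOD of lymphocyte
    internal controls to obtain DNA indices (DI), builds DI histograms,
    extracts per-sample peak DI, classifies ploidy against a mild-aneuploidy
    threshold (DI > 1.1), and compares condition groups with one-tailed
    unpaired t-tests. Includes a synthetic Feulgen-slide simulator with
    Beer-Lambert ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
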