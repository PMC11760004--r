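Package: marblefine
Title: Marbling Fineness Quantification from Beef Cross-Section Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments intramuscular fat (marbling) particles from sirloin
    cross-section images by per-image Otsu thresholding inside a
    region-of-interest mask, measures particle geometry (area, perimeter,
    cumulative A50/P50 statistics), and computes a family of marbling
    fineness indices, centrally the tile-grid heterogeneity index F7: the
    sample standard deviation across step x step tiles of the per-tile
    fat-area ratio. Includes group comparison statistics (Welch t test,
    one-way ANOVA, bootstrap confidence intervals), a step-size sweep for
    selecting the tile resolution, and a seeded synthetic marbling image
    generator (Boolean model of deformed disks) for end-to-end validation
    when real graded images are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
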