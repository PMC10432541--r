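Package: fostopo
Title: Topographic Analysis of Learning-Induced c-Fos Expression in Dorsal CA1
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for topographic quantification of immediate-early-gene
    (c-Fos) expression over a regular ROI grid covering the dorsal CA1
    pyramidal layer. Provides the canonical 12-section antero-posterior by
    8-12 ROI proximo-distal grid with its eight-subregion scheme; count-table
    input/output; a calibrated synthetic cohort generator (negative-binomial
    counts with subregional effect fields, animal effects, spatial random
    fields and missing-ROI dropout) plus a synthetic stained-section renderer
    with ground truth; automated nucleus detection (robust background,
    size-filtered connected components) and per-ROI counting; group-level
    heat-map matrices, subregion ANOVA with Tukey HSD, frequency-bin
    Mann-Whitney comparisons; a fixed-radius high-count neighbor clustering
    rule; a cross-animal shared-position statistic; and regularized quadratic
    discriminant classification of training protocol with cross-validated
    accuracy and Kruskal-Wallis feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
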