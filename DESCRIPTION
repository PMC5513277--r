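Package: songdiff
Title: Song Differentiation Analysis for Sky-Island Songbird Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify population-level differentiation in birdsong
    from note-level spectrogram annotations (Raven-style selection tables).
    Derives fourteen song-level spectral traits including two indicators of
    complex vocal mechanisms (internote intervals shorter than a minibreath
    and temporal note overlap), measures syntax complexity via the Song
    Variety Index and new/modified/old/same bout versatility categories,
    builds a cross-individual song-type library, runs a multivariate
    population-differentiation battery (PCA, nested MANOVA/ANOVA, canonical
    discriminant analysis, NMDS, Kruskal-Wallis with Dunn-Bonferroni post
    hoc), and relates song distances to geographic distance, dispersal
    barriers, and genetic differentiation with Mantel and partial Mantel
    permutation tests. Includes a hierarchical synthetic song-bout simulator
    so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    geosphere,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
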