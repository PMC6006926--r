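Package: apicomp
Title: Compositional Analysis of the Aging Honey Bee Queen Gut Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute-abundance analysis of 16S rRNA amplicon
    surveys of the honey bee queen alimentary tract. Converts OTU read
    proportions to estimated bacterial cell counts using taxon-specific 16S
    gene copy numbers and qPCR community sizes, applies centered log-ratio
    (CLR) transforms, and provides the multivariate statistics used to
    relate microbiota structure to chronological age, queen source, and
    biological age measured as fat-body protein carbonyl content: Pillai
    MANOVA/MANCOVA with Tukey post hocs, Wilcoxon rank-sum screens with
    multiplicity corrections, CLR-based PCA biplots, ANOSIM, distance-based
    linear models, and SparCC correlation networks with bootstrap
    pseudo-p-values. A configurable synthetic-study generator emulating the
    63-queen, four-niche design supports end-to-end testing and power
    analysis without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
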