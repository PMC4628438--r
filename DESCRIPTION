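Package: aflpdiver
Title: Dominant-Marker Diversity Analysis for AFLP Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Replicate-based band calling, locus repeatability filtering,
    Dice-distance UPGMA clustering with locus-bootstrap support, clonal
    haplotype identification and chi-square frequency tests for dominant
    AFLP marker data, as used to resolve intraspecific diversity in
    entomopathogenic fungal isolate collections. Includes a synthetic
    fragment-intensity simulator with known clonal ground truth, readers
    and writers for intensity tables, binary scoring matrices, PHYLIP
    distance matrices and Newick trees with bootstrap support, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    mclust,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
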