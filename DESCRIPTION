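Package: stcap
Title: Analysis of Ape Subterminal Heterochromatic Caps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the subterminal heterochromatic caps of
    African great ape chromosomes. Detects and variant-types the 32 bp
    pCht/StSat satellite unit, derives satellite arrays and segmental
    duplication (SD) spacer intervals, classifies higher-order cap blocks by
    two-step k-means, clusters chromosome arms by satellite variant
    composition with bootstrap support, builds neighbor-joining phylogenies
    of SD spacers with strict-clock time calibration, tests for ectopic
    recombination with breakpoint permutation and Robinson-Foulds shift
    procedures, calls insertions and runs enrichment tests at
    euchromatin-heterochromatin boundaries, merges and profiles CpG
    methylation, and simulates cap-like genomes with complete ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
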