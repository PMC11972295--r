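Package: organotrope
Title: Cytogenetic Organotropism Analysis of Colorectal Cancer Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for chromosomal-imbalance (CI) profiles of
    colorectal cancer metastases to liver, lung, and brain. Provides a data
    model for band-resolution CI matrices with the standard exclusion regions,
    a simplified arm-level aneuploidy caller for segmented copy-number data,
    exact site-enrichment ("organotropic") mapping with ternary coordinates,
    an exact probabilistic co-occurrence model for binary genomic events,
    maximum-likelihood oncogenetic trees with nine early-to-late event timing
    classes, per-patient maximum-parsimony phylogenies with trunk, branch and
    sub-branch CI scoring, a stratified permutation trend test, and a
    tumor-evolution cohort simulator supplying ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
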