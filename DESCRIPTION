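Package: gelpfam
Title: Gene Family Evolution Analysis for GDSL Esterase/Lipase Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for plant gene-family expansion studies
    of the kind applied to the soybean GDSL esterase/lipase (GELP) family:
    iterative profile-based family identification with E-value calibration,
    duplicate-pair classification (tandem versus WGD/segmental) with
    Nei-Gojobori Ka/Ks estimation, neighbor-joining phylogenies under the
    Poisson correction with pairwise deletion and bootstrap support,
    an intron-position gain/loss model with subfamily "basic forms" and
    ancestral-structure reconstruction, and expression/regulatory filtering
    stages (log2(FPKM+1) transforms, fold-change/p-value response calls,
    2^-ddCt relative quantification, promoter cis-element scanning).
    A synthetic-data module simulates gene families with known duplication
    history, selection pressure, intron evolution and expression structure
    so that every stage is testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
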