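Package: winefp
Title: Wine DNA Fingerprinting and Varietal Admixture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of residual grapevine DNA in wine typed at microsatellite
    (SSR) loci. Builds validated wine allele profiles from replicated
    capillary-electrophoresis peak observations (reference-based size
    calibration, allele binning, cross-replica consensus), computes panel
    discrimination statistics (per-locus and cumulative probability of
    identity, random match probability), allele-sharing distances between
    wines and grapevine reference varieties, Neighbor-Joining and
    average-linkage trees with multiscale-bootstrap cluster support (BP and
    approximately unbiased p-values), candidate-variety presence calls for
    blended wines with PCA ordination, and a multiplex-network data
    integration model based on supra-adjacency communicability. Includes a
    synthetic-data generator with age- and proportion-dependent allele
    dropout so the full pipeline is testable without wet-lab genotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
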