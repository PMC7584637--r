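Package: bgcsel
Title: Selection Analysis for Biosynthetic Gene Clusters from SNP Panels and
    Ortholog Alignments
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-genetic selection scans for physically clustered
    metabolic genes (biosynthetic gene clusters). Implements linkage
    disequilibrium (r^2) enrichment across focal genomic neighborhoods with
    tandem-locus merging and LOESS decay curves; pairwise dN/dS estimation by
    Nei-Gojobori counting and by maximum likelihood under a single-ratio
    Goldman-Yang codon model with a likelihood-ratio test against neutrality;
    the McDonald-Kreitman test family (standard, FWW low-frequency correction,
    and the extended variant correcting for weakly deleterious segregating
    variants); and seeded forward Wright-Fisher simulators of sweep and
    neutral SNP panels, codon-pair alignments, and polymorphism/divergence
    tables for validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
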