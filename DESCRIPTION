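Package: ighvaudit
Title: Auditing Immunoglobulin Heavy-Chain V Germline Reference Databases
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing immunoglobulin heavy-chain variable (IGHV)
    germline gene reference databases. Compares databases for exact and
    near-exact allele overlap, groups alleles into genes by edit-distance
    clustering, locates database sequences in genomic assembly contigs,
    assigns expressed antibody repertoire reads to germline alleles to
    quantify somatic hypermutation (SHM), measures the SHM overestimation
    caused by genes missing from a reference database, infers simplified
    individualized genotypes from IgM libraries, and performs haplotype
    inference anchored on a heterozygous J gene. Includes a synthetic
    germline-locus and VDJ-repertoire simulator with full ground truth for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
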