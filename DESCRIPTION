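Package: quartetcoal
Title: Fragment-Length Effects on Multispecies Coalescent Inference in
    Four-Taxon Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference toolkit for studying how sequence
    fragment length interacts with the multispecies coalescent (MSC) in
    four-species phylogenies.  Simulates gene genealogies under a
    four-taxon MSC (including multi-allele designs with per-branch
    effective population sizes), evolves nucleotide sequences along
    genealogies, assembles multi-segment loci whose internal segments may
    follow different genealogies (a surrogate for linkage heterogeneity
    induced by chromosomal shuffling), samples fragments of increasing
    length classes, infers quartet gene trees by maximum likelihood and
    parsimony, classifies "1100"-type phylogenetically informative sites,
    and summarises topology discordance, mismatch imbalance, and
    internode lengths in coalescent units via the Pamilo-Nei match
    probability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
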