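Package: venomdyn
Title: Evolutionary Dynamics of Venom Toxin Expression and Copy Number
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how venom expression phenotypes evolve across
    a phylogeny and how a clustered toxin gene family varies within a species.
    Builds family-level venom composition phenotypes from transcript
    expression tables, classifies dominant toxin families, and fits Brownian
    motion, Ornstein-Uhlenbeck, early-burst and pulsed (jump-normal Levy)
    models of continuous trait evolution with AIC-weight model selection,
    maximum-likelihood ancestral state reconstruction, Pagel's lambda,
    multivariate phylogenetic covariance with parametric-bootstrap intervals
    and phylomorphospace ordination. A microevolution toolkit recovers
    sequence variants of a highly duplicated toxin gene from mapped read
    pairs, performs amplicon haplotyping with abundance/prevalence variant
    calling and core-haplotype deduction, estimates diploid copy number from
    multiplex qPCR triplicates by the delta-delta-Ct method, and analyses
    toxin locus architecture (tandem duplication units, minimal block-edit
    haplotype comparison, non-B DNA motif scanning). A synthetic-data module
    generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    car,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
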