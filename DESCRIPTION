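Package: mhclineage
Title: Allelic Lineage Divergence and Persistence Analysis for MHC Coding
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the long-term evolution of allelic lineages
    at classical MHC loci (e.g. HLA-DRB1) from aligned coding sequences:
    screening of putative recombinant alleles by a sliding-window binomial
    clustering test, codon-level synonymous and nonsynonymous distances by
    the modified Nei-Gojobori method with Jukes-Cantor correction,
    divergence-time and TMRCA estimation under a neutral synonymous clock,
    classification of segregating synonymous sites with four-gamete
    compatibility analysis, parsimony mapping of synonymous substitutions
    onto a phylogeny with tree-path recounting of substitution numbers, and
    coalescent probabilities for the number of ancestral allelic lineages.
    A codon-sequence simulator with region-specific selection and optional
    splice recombinants provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
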