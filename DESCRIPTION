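Package: pestiscan
Title: Profile-HMM Detection of Bacterial Pesticidal Proteins and Their Genetic Context
Version: 0.1.0
Authors@R: person("pestiscan", "developers", role = c("aut", "cre"),
    email = "pestiscan@example.org")
Description: Builds curated profile hidden Markov models of bacterial
    pesticidal-protein (toxin) families from raw sequence sets: redundancy
    removal at 100% identity, all-vs-all Smith-Waterman similarity graphs,
    Markov clustering, progressive family alignment and HMM estimation with
    per-model gathering-cutoff calibration from bit-score distributions.
    Detects and classifies candidate toxins in protein sets or GenBank
    genomes by Viterbi/forward scoring, reports profile alignments and
    nearest-neighbour trees, extracts the genomic regions flanking each hit,
    re-annotates them uniformly and renders EasyFig-style identity-block
    comparisons. Includes a seeded synthetic-data generator for protein
    families and toxin-cassette genomes, and a sensitivity/specificity
    benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
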