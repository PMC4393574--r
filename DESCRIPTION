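Package: gshuffle
Title: Forward-Time Simulation and Sequencing Analysis of Genome-Shuffled Yeast Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deconstructing the genetics of genome-shuffled
    Saccharomyces cerevisiae populations evolved by recursive pool-wise
    mating under selection. Provides a forward-time simulator of the
    genome-shuffling protocol (UV mutagenesis, truncation selection,
    pool mating, meiosis with Haldane recombination), pooled-amplicon
    allele-frequency estimation with a matched-control false-positive
    variant filter, codon-level mutation effect classification with
    SIFT-threshold phenotype prediction, multi-round allele-frequency
    trajectory classification, co-origin (linked founder) cluster
    inference, population-versus-isolate frequency reconciliation, and
    candidate-mutation ranking, together with an end-to-end pipeline
    and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
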