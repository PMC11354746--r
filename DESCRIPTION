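Package: crhaplo
Title: Mitochondrial Control-Region Haplotype Variability, Diversity
    Decomposition and Median-Joining Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for aligned mitochondrial control-region
    (and protein-coding) sequence data in population samples: haplotype
    collapsing with IUPAC-ambiguity and NUMT-artefact resolution policies,
    segregating-site classification and sliding-window variability
    profiles with conserved-block and poly-T homopolymer detection,
    uncorrected p and Tamura 3-parameter genetic distances with column
    bootstrap standard errors, Nei-style nucleotide-diversity
    decomposition within and among populations (pi, pi_S, pi_T, delta_ST,
    N_ST), strict molecular-clock divergence dating, substitution
    rate-ratio comparison between linked markers, and from-scratch
    median-joining haplotype networks. Includes a sequence simulator with
    transition/transversion and G+C-content bias for validating every
    stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
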