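Package: obake
Title: Population Structure, Diversity, and Interspecific Hybrid Detection
    for Wild Rice Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing biallelic SNP and plastid microsatellite
    genotypes of Oryza longistaminata and its AA-genome relatives: a
    genotype filter cascade (top-two alleles, heterozygosity cap, allelic
    depth bounds, minor-allele-frequency and site-presence thresholds),
    Bayesian admixture-model ancestry inference (unsupervised and
    supervised Gibbs samplers plus a deterministic EM mode), Evanno
    delta-K model selection across replicate runs, discriminant analysis
    of principal components with BIC-based cluster-number selection,
    spatial PCA over a minimum-spanning connectivity network of
    collection sites, sample-size-corrected gene diversity, F_ST, F_IS
    and pairwise Jost's D, identity-by-state distances and
    neighbor-joining trees with outgroup rooting, plastid haplotype
    collapsing and minimum-spanning networks, and classification of
    putative interspecific hybrids against thresholds calibrated from
    control recombinant inbred lines. A synthetic-panel generator with
    full ground truth (hierarchical Balding-Nichols allele frequencies,
    geographic admixture gradients, inbreeding, hybrid pedigrees,
    maternally inherited plastid haplotypes, missing-data and read-depth
    models) supports end-to-end validation of every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    igraph,
    MASS,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
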