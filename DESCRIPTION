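Package: canpopgen
Title: Genomic Characterization of Canine Breed Diversity and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end toolkit for SNP-array characterization of dog breeds:
    PLINK text/binary genotype input and output, marker and sample quality
    control, pedigree numerator relationship matrices and inbreeding, runs of
    homozygosity and the genomic inbreeding coefficient F_ROH, linkage
    disequilibrium decay with Sved-equation effective-population-size
    trajectories, Yang-estimator genomic relationship matrices,
    identity-by-state distances, classical multidimensional scaling,
    neighbor-joining trees, and EM fitting of the admixture model with
    cross-validated choice of the number of ancestral populations. Includes
    generators for synthetic genotype panels (gene dropping down pedigrees,
    Wright-Fisher populations, Balding-Nichols admixture) with known truth,
    so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
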