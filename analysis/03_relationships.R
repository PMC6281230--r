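#!/usr/bin/env Rscript
# Stage 3: pedigree vs genomic relationships in the focal breed.
#
# Numerator relationship matrix A and pedigree inbreeding from the
# pedigree; allele-frequency-scaled GRM and IBS distances from the QC'd
# genotypes; their agreement (the Pearson correlation between matched
# off-diagonal entries) summarizes how well markers recover the pedigree.

suppressPackageStartupMessages(library(canpopgen))
ind <- "results/data"
out <- "results/relationships"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ped <- read_pedigree(file.path(ind, "focal_pedigree.tsv"), header = TRUE)
ds <- read_plink_binary(file.path(ind, "focal_qc.bed"),
                        file.path(ind, "focal_qc.bim"),
                        file.path(ind, "focal_qc.fam"))

A <- additive_relationship_matrix(ped)
fped <- pedigree_inbreeding(ped)
gen <- generation_number(ped, focal = ds$sample_ids)
pergen <- per_generation_inbreeding(ped)
cat(sprintf("pedigree: %d animals, mean F = %.3f (SD %.3f), mean depth %.1f generations\n",
            nrow(ped), attr(fped, "mean_F"), attr(fped, "sd_F"),
            attr(gen, "mean_depth")))

G <- genomic_relationship_matrix(ds)
D <- ibs_distance_matrix(ds)
r_off <- matrix_correlation(G, A, mode = "off_diagonal")
r_all <- matrix_correlation(G, A, mode = "all")
cat(sprintf("G vs A correlation: %.3f (off-diagonal), %.3f (incl. diagonal)\n",
            r_off, r_all))

# realized autozygosity from the simulation truth vs pedigree expectation
truth <- utils::read.table(file.path(ind, "focal_truth_F.tsv"),
                           header = TRUE, colClasses = c("character",
                                                         "numeric"))
shared <- intersect(truth$animal, fped$animal)
cat(sprintf("pedigree F vs realized autozygosity: r = %.3f\n",
            cor(fped$F[match(shared, fped$animal)],
                truth$realized_F[match(shared, truth$animal)])))

utils::write.table(fped, file.path(out, "pedigree_F.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(pergen, file.path(out, "per_generation_F.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(animal = rownames(A), A,
                              check.names = FALSE),
                   file.path(out, "A_matrix.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(sample_id = rownames(G), G,
                              check.names = FALSE),
                   file.path(out, "G_matrix.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(sample_id = rownames(D), D,
                              check.names = FALSE),
                   file.path(out, "ibs_distance.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(statistic = c("r_G_A_offdiag", "r_G_A_all"),
             value = c(r_off, r_all)),
  file.path(out, "correlations.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
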