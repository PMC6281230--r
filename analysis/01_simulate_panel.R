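#!/usr/bin/env Rscript
# Stage 1: build the synthetic study substrate.
#
# Two datasets, mirroring a typical breed-characterization design:
#  * focal: a single pedigreed breed (60 dogs bred from 20 founders over
#    ~5 generations), genotypes gene-dropped through the pedigree so that
#    pedigree inbreeding, autozygosity and ROH have a known truth;
#  * panel: a 3-breed SNP panel (15 dogs each, Fst = 0.1) for the
#    between-population analyses (IBS distances, MDS, NJ tree, admixture).
#
# Outputs (results/data/): PLINK binary files, the pedigree, and truth
# tables (realized autozygosity per animal; breed labels).

suppressPackageStartupMessages(library(canpopgen))
set.seed(1)
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## focal breed: random pedigree over 20 founders
n_total <- 70
nf <- 12
sire <- dam <- rep(NA_character_, n_total)
for (i in (nf + 1):n_total) {
  # parents drawn from a recent window: deepens the pedigree and yields
  # realistic within-breed inbreeding from repeated close matings
  lo <- max(1L, i - 25L)
  sire[i] <- as.character(sample(lo:(i - 1L), 1))
  dam[i] <- as.character(sample(lo:(i - 1L), 1))
}
ped <- pedigree_table(as.character(seq_len(n_total)), sire, dam)
# founders sampled from a finite (N = 80) population after 120 generations
# of drift, so the breed carries realistic background LD, not just the
# family LD induced by the recent pedigree; marker density is chosen so
# the post-drift map still supports ROH detection (~75 kb spacing)
wf <- sim_wright_fisher(N = 80, generations = 120, n_sample = nf,
                        m = 30400, chromosomes = 38, chrom_length_bp = 4e7,
                        init_freq = c(0.1, 0.9), seed = 2)
founders <- list(dataset = wf$dataset, haplotypes = wf$haplotypes)
gd <- gene_drop(founders, ped, seed = 3)
write_genotypes(gd$dataset, file.path(out, "focal"), "binary")
utils::write.table(ped, file.path(out, "focal_pedigree.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(gd$truth, file.path(out, "focal_truth_F.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("focal breed: %d animals x %d SNPs; mean realized F %.3f\n",
            nrow(gd$dataset$dosage), nrow(gd$dataset$map),
            mean(gd$truth$realized_F)))

## multi-breed panel
panel <- sim_breed_panel(n_per_breed = 15, breeds = 3, m = 3000,
                         fst = 0.1, chromosomes = 10, seed = 4)
write_genotypes(panel$dataset, file.path(out, "panel"), "binary")
utils::write.table(
  data.frame(sample_id = panel$dataset$sample_ids,
             breed = panel$truth$breed),
  file.path(out, "panel_breeds.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("panel: %d dogs in %d breeds x %d SNPs\n",
            nrow(panel$dataset$dosage), 3, nrow(panel$dataset$map)))
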