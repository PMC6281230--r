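#!/usr/bin/env Rscript
# Stage 2: marker and sample quality control.
#
# Filters follow standard SNP-array practice: unmapped markers out,
# autosomes only, call rate >= 95%, then MAF (5% for the within-breed
# dataset, 1% for the merged panel), finally samples with > 10% missing
# genotypes. Survivor counts per step go to results/qc/.

suppressPackageStartupMessages(library(canpopgen))
ind <- "results/data"
out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

focal <- read_plink_binary(file.path(ind, "focal.bed"),
                           file.path(ind, "focal.bim"),
                           file.path(ind, "focal.fam"))
qc_f <- apply_qc(focal, qc_thresholds(min_maf = 0.05))
utils::write.table(qc_f$report, file.path(out, "focal_qc.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("focal QC:\n")
print(qc_f$report)
write_genotypes(qc_f$dataset, file.path(ind, "focal_qc"), "binary")

panel <- read_plink_binary(file.path(ind, "panel.bed"),
                           file.path(ind, "panel.bim"),
                           file.path(ind, "panel.fam"))
qc_p <- apply_qc(panel, qc_thresholds(min_maf = 0.01))
utils::write.table(qc_p$report, file.path(out, "panel_qc.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("panel QC:\n")
print(qc_p$report)
write_genotypes(qc_p$dataset, file.path(ind, "panel_qc"), "binary")
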