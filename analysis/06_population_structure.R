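#!/usr/bin/env Rscript
# Stage 6: between-breed structure on the multi-breed panel.
#
# IBS distances -> classical MDS (3 dimensions) and a breed-level NJ tree
# (breed-mean distances); admixture-model clustering with 5-fold
# cross-validation choosing K, then the full fit at the selected K.

suppressPackageStartupMessages(library(canpopgen))
ind <- "results/data"
out <- "results/structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ds <- read_plink_binary(file.path(ind, "panel_qc.bed"),
                        file.path(ind, "panel_qc.bim"),
                        file.path(ind, "panel_qc.fam"))
breeds <- utils::read.table(file.path(ind, "panel_breeds.tsv"),
                            header = TRUE,
                            colClasses = "character")
breed <- breeds$breed[match(ds$sample_ids, breeds$sample_id)]

D <- ibs_distance_matrix(ds)
mds <- classical_mds(D, k = 3)
utils::write.table(
  data.frame(sample_id = rownames(mds$coords), breed = breed,
             mds$coords, check.names = FALSE),
  file.path(out, "mds_coordinates.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

nwk <- nj_tree(breed_distance_matrix(D, breed))
writeLines(as.character(nwk), file.path(out, "nj_breeds.nwk"))
cat("breed NJ tree:", as.character(nwk), "\n")

cv <- admixture_cv(ds, K_list = 1:5, folds = 5, seed = 7)
cat("cross-validation errors:\n")
print(cv$table)
cat("selected K =", cv$selected_K, "\n")
fit <- admixture_fit(ds, cv$selected_K, seed = 7, tol = 1e-5,
                     max_iter = 2000)
cat(sprintf("admixture fit: loglik %.1f after %d iterations\n",
            fit$loglik, fit$iterations))
# dominant cluster per breed (label-switching aside, each breed should
# load on its own component in an unadmixed panel)
agg <- stats::aggregate(fit$Q, by = list(breed = breed), FUN = mean)
print(agg, digits = 2)

utils::write.table(cv$table, file.path(out, "admixture_cv.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(sample_id = rownames(fit$Q), breed = breed, fit$Q,
             check.names = FALSE),
  file.path(out, "admixture_Q.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
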