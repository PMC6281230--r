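#' Run configuration for the full characterization pipeline
#'
#' @param qc a [qc_thresholds()].
#' @param roh a [roh_params()].
#' @param ne an [ne_params()].
#' @param ld_max_distance_bp cap for syntenic pair distances.
#' @param ld_bin_edges distance-bin boundaries in bp.
#' @param mds_k MDS dimensions.
#' @param K_list admixture K values to cross-validate.
#' @param cv_folds cross-validation folds.
#' @param min_breed_size breeds below this size are excluded from per-breed
#'   statistics (default 10).
#' @param seed master RNG seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(qc = qc_thresholds(), roh = roh_params(),
                       ne = ne_params(),
                       ld_max_distance_bp = 1e7,
                       ld_bin_edges = seq(0, 1e7, by = 2.5e5),
                       mds_k = 3, K_list = 1:4, cv_folds = 5,
                       min_breed_size = 10, seed = 1) {
  structure(list(qc = qc, roh = roh, ne = ne,
                 ld_max_distance_bp = ld_max_distance_bp,
                 ld_bin_edges = ld_bin_edges, mds_k = mds_k,
                 K_list = K_list, cv_folds = cv_folds,
                 min_breed_size = min_breed_size, seed = seed),
            class = "run_config")
}

#' Run the full breed-characterization pipeline
#'
#' Executes the stages in dependency order: QC, pedigree relationships
#' (when a pedigree is supplied), genomic relationship and IBS distance
#' matrices, ROH and F_ROH, LD decay and the Ne trajectory, MDS, NJ tree
#' and admixture with cross-validated K. Per-breed summaries (mean F_ROH,
#' recent Ne) are produced when the sample metadata carries a `breed`
#' column, restricted to breeds with at least `min_breed_size` samples.
#' Results are optionally written as TSV/newick files under `out_dir`.
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [run_config()].
#' @param pedigree optional `pedigree_table`.
#' @param out_dir optional output directory for artifact files.
#' @param structure run the MDS/NJ/admixture stage (the slowest) or skip
#'   it.
#' @return list of class `run_report` with elements `qc_report`, `summary`
#'   (named numerics), and the stage outputs (`A`, `F_pedigree`, `G`,
#'   `ibs_D`, `roh`, `froh`, `ld_decay`, `ne`, `mds`, `nj_newick`, `cv`,
#'   `admixture`, `per_breed`, `manifest`).
#' @export
run_pipeline <- function(dataset, config = run_config(), pedigree = NULL,
                         out_dir = NULL, structure = TRUE) {
  res <- list()
  qc <- apply_qc(dataset, config$qc)
  ds <- qc$dataset
  res$qc_report <- qc$report
  summary <- c(n_samples = length(ds$sample_ids), n_markers = nrow(ds$map))

  if (!is.null(pedigree)) {
    res$A <- additive_relationship_matrix(pedigree)
    res$F_pedigree <- pedigree_inbreeding(pedigree)
    fg <- res$F_pedigree$F[res$F_pedigree$animal %in% ds$sample_ids]
    summary["mean_pedigree_F"] <- mean(fg)
    summary["sd_pedigree_F"] <- stats::sd(fg)
  }

  res$G <- genomic_relationship_matrix(ds)
  res$ibs_D <- ibs_distance_matrix(ds)
  if (!is.null(pedigree)) {
    summary["r_g_a_offdiag"] <-
      matrix_correlation(res$G, res$A, mode = "off_diagonal")
    summary["r_g_a_all"] <- matrix_correlation(res$G, res$A, mode = "all")
  }

  res$roh <- detect_roh(ds, config$roh)
  res$froh <- froh(res$roh, ds)
  summary["mean_F_ROH"] <- mean(res$froh$F_ROH)
  summary["sd_F_ROH"] <- stats::sd(res$froh$F_ROH)
  if (!is.null(pedigree)) {
    shared <- intersect(res$froh$sample_id, res$F_pedigree$animal)
    fr <- res$froh$F_ROH[match(shared, res$froh$sample_id)]
    fp <- res$F_pedigree$F[match(shared, res$F_pedigree$animal)]
    if (length(shared) >= 3 && stats::sd(fr) > 0 && stats::sd(fp) > 0)
      summary["cor_F_FROH"] <- stats::cor(fr, fp)
  }

  pairs <- pairwise_r2(ds, config$ld_max_distance_bp)
  if (nrow(pairs)) {
    res$ld_decay <- ld_decay(pairs, config$ld_bin_edges)
    res$ne <- estimate_ne(res$ld_decay, config$ne,
                          n_samples = length(ds$sample_ids))
    if (nrow(res$ne)) {
      summary["recent_Ne"] <- res$ne$Ne[1]
      summary["recent_Ne_t"] <- res$ne$t_generations[1]
    }
  }

  if (structure) {
    res$mds <- classical_mds(res$ibs_D, k = config$mds_k)
    breeds <- if (!is.null(ds$metadata$breed)) ds$metadata$breed else NULL
    if (!is.null(breeds) && length(unique(breeds)) >= 3) {
      res$nj_newick <- nj_tree(breed_distance_matrix(res$ibs_D, breeds))
    } else if (length(ds$sample_ids) >= 3) {
      res$nj_newick <- nj_tree(res$ibs_D)
    }
    res$cv <- admixture_cv(ds, K_list = config$K_list,
                           folds = config$cv_folds, seed = config$seed)
    summary["selected_K"] <- res$cv$selected_K
    res$admixture <- admixture_fit(ds, res$cv$selected_K,
                                   seed = config$seed)
    summary["admixture_loglik"] <- res$admixture$loglik
  }

  if (!is.null(ds$metadata$breed)) {
    res$per_breed <- per_breed_summary(ds, res, config)
  }

  res$summary <- summary
  if (!is.null(out_dir)) res$manifest <- write_report(res, ds, out_dir)
  class(res) <- "run_report"
  res
}

## Internal: per-breed F_ROH and recent Ne for breeds of sufficient size
per_breed_summary <- function(ds, res, config) {
  breeds <- ds$metadata$breed
  counts <- table(breeds)
  keep <- names(counts)[counts >= config$min_breed_size]
  rows <- list()
  for (b in keep) {
    sel <- which(breeds == b)
    sub <- ds
    sub$dosage <- ds$dosage[sel, , drop = FALSE]
    sub$sample_ids <- ds$sample_ids[sel]
    sub$metadata <- ds$metadata[sel, , drop = FALSE]
    mf <- mean(res$froh$F_ROH[match(sub$sample_ids, res$froh$sample_id)])
    ne_recent <- NA_real_
    pr <- pairwise_r2(sub, config$ld_max_distance_bp)
    if (nrow(pr)) {
      dec <- ld_decay(pr, config$ld_bin_edges)
      net <- estimate_ne(dec, config$ne, n_samples = length(sel))
      if (nrow(net)) ne_recent <- net$Ne[1]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      breed = b, n = length(sel), mean_F_ROH = mf, recent_Ne = ne_recent)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

## Internal: write stage outputs as TSV/newick; returns manifest data.frame
write_report <- function(res, ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wtsv <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  wtsv(res$qc_report, "qc_report.tsv")
  wtsv(data.frame(statistic = names(res$summary),
                  value = unname(res$summary)), "summary.tsv")
  if (!is.null(res$froh)) wtsv(res$froh, "froh.tsv")
  if (!is.null(res$roh)) wtsv(as.data.frame(res$roh), "roh_segments.tsv")
  if (!is.null(res$ld_decay)) wtsv(res$ld_decay, "ld_decay.tsv")
  if (!is.null(res$ne)) wtsv(res$ne, "ne_trajectory.tsv")
  if (!is.null(res$G))
    wtsv(data.frame(sample_id = rownames(res$G), res$G,
                    check.names = FALSE), "grm.tsv")
  if (!is.null(res$ibs_D))
    wtsv(data.frame(sample_id = rownames(res$ibs_D), res$ibs_D,
                    check.names = FALSE), "ibs_distance.tsv")
  if (!is.null(res$A))
    wtsv(data.frame(animal = rownames(res$A), res$A,
                    check.names = FALSE), "pedigree_A.tsv")
  if (!is.null(res$F_pedigree)) wtsv(res$F_pedigree, "pedigree_F.tsv")
  if (!is.null(res$mds))
    wtsv(data.frame(sample_id = rownames(res$mds$coords),
                    res$mds$coords, check.names = FALSE), "mds.tsv")
  if (!is.null(res$cv)) wtsv(res$cv$table, "admixture_cv.tsv")
  if (!is.null(res$admixture))
    wtsv(data.frame(sample_id = rownames(res$admixture$Q),
                    res$admixture$Q, check.names = FALSE), "admixture_Q.tsv")
  if (!is.null(res$per_breed)) wtsv(res$per_breed, "per_breed.tsv")
  if (!is.null(res$nj_newick)) {
    path <- file.path(out_dir, "nj_tree.nwk")
    writeLines(as.character(res$nj_newick), path)
    files <- c(files, path)
  }
  data.frame(file = basename(files),
             md5 = vapply(files, function(f)
               as.character(tools::md5sum(f)), character(1)),
             row.names = NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-22s %s\n", nm, format(x$summary[[nm]], digits = 4)))
  invisible(x)
}
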