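#' QC thresholds
#'
#' Container of marker/sample filter settings. Defaults follow common
#' SNP-array practice for breed characterization: markers with call rate
#' below 95% or minor allele frequency below 1% are removed, samples with
#' more than 10% missing genotypes are removed, and only markers mapped to
#' the 38 canine autosomes are retained. All comparisons are strict
#' (call rate `< min_call_rate` removes, MAF `< min_maf` removes, sample
#' missingness `> max_sample_missing` removes).
#'
#' @param min_call_rate minimum marker call rate (fraction).
#' @param min_maf minimum minor allele frequency.
#' @param max_sample_missing maximum per-sample missing fraction.
#' @param autosomes_only drop markers whose chromosome code is outside
#'   `autosome_range`.
#' @param drop_unmapped drop markers with chromosome code 0 / negative /
#'   missing position.
#' @param autosome_range integer range of autosomal chromosome codes.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          max_sample_missing = 0.10, autosomes_only = TRUE,
                          drop_unmapped = TRUE, autosome_range = c(1L, 38L)) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_sample_missing = max_sample_missing,
                 autosomes_only = autosomes_only,
                 drop_unmapped = drop_unmapped,
                 autosome_range = as.integer(autosome_range)),
            class = "qc_thresholds")
}

#' Marker quality control
#'
#' Applies marker filters in a fixed order — unmapped markers, non-autosomal
#' markers, call rate, then MAF (MAF computed over non-missing calls on the
#' markers surviving the earlier steps) — and itemizes removals per step.
#'
#' @param dataset a [genotype_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `dataset` (filtered) and `report` (data.frame
#'   with one row per filter step: step, removed, retained).
#' @export
marker_qc <- function(dataset, thresholds = qc_thresholds()) {
  if (nrow(dataset$map) == 0) stop("empty dataset")
  keep <- rep(TRUE, nrow(dataset$map))
  steps <- character(0)
  removed <- integer(0)
  mark <- function(drop, label) {
    drop <- drop & keep
    keep <<- keep & !drop
    steps <<- c(steps, label)
    removed <<- c(removed, sum(drop))
  }
  chrom <- dataset$map$chrom
  if (thresholds$drop_unmapped)
    mark(is.na(chrom) | chrom <= 0L | is.na(dataset$map$pos_bp), "unmapped")
  if (thresholds$autosomes_only)
    mark(!(chrom >= thresholds$autosome_range[1] &
             chrom <= thresholds$autosome_range[2]), "non_autosomal")
  call_rate <- colMeans(!is.na(dataset$dosage))
  mark(call_rate < thresholds$min_call_rate, "call_rate")
  # MAF over non-missing calls, evaluated only on still-surviving markers
  p <- colMeans(dataset$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # markers with zero calls are monomorphic-by-absence
  mark(maf < thresholds$min_maf, "maf")
  report <- data.frame(step = steps, removed = removed,
                       retained = nrow(dataset$map) - cumsum(removed))
  if (!any(keep)) warning("marker QC removed all markers")
  out <- dataset
  out$map <- dataset$map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  out$dosage <- dataset$dosage[, keep, drop = FALSE]
  list(dataset = out, report = report)
}

#' Sample quality control
#'
#' Removes samples whose missing-genotype fraction exceeds
#' `max_sample_missing` (strict `>`). Ordinarily applied after
#' [marker_qc()], mirroring the usual filter sequence.
#'
#' @inheritParams marker_qc
#' @return list with `dataset` and `report` (one row).
#' @export
sample_qc <- function(dataset, thresholds = qc_thresholds()) {
  if (length(dataset$sample_ids) == 0) stop("empty dataset")
  missfrac <- rowMeans(is.na(dataset$dosage))
  keep <- missfrac <= thresholds$max_sample_missing
  if (!any(keep)) warning("sample QC removed all samples")
  out <- dataset
  out$dosage <- dataset$dosage[keep, , drop = FALSE]
  out$sample_ids <- dataset$sample_ids[keep]
  if (!is.null(out$metadata)) {
    out$metadata <- out$metadata[keep, , drop = FALSE]
    rownames(out$metadata) <- NULL
  }
  report <- data.frame(step = "sample_missing", removed = sum(!keep),
                       retained = sum(keep))
  list(dataset = out, report = report)
}

#' Full QC pass: markers then samples
#'
#' @inheritParams marker_qc
#' @return list with `dataset` and combined `report`.
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  mq <- marker_qc(dataset, thresholds)
  sq <- sample_qc(mq$dataset, thresholds)
  list(dataset = sq$dataset, report = rbind(mq$report, sq$report))
}
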