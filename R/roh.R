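#' ROH detection parameters
#'
#' Sliding-window criteria for run-of-homozygosity detection: 50-SNP windows
#' allowing at most two heterozygous and two missing calls; a SNP is
#' eligible when the proportion of passing windows among the windows that
#' contain it (its hit rate) exceeds 0.05; candidate runs of eligible SNPs
#' are split at inter-SNP gaps above 100 kb and must contain at least 50
#' SNPs, span at least 100 kb, and have a density of at least 1 SNP per
#' 50 kb.
#'
#' @param window_snps window length in SNPs.
#' @param window_max_het maximum heterozygous calls per passing window.
#' @param window_max_missing maximum missing calls per passing window.
#' @param hit_rate_threshold eligibility threshold (strict `>`).
#' @param min_snps minimum SNPs per run.
#' @param min_length_bp minimum run length in bp.
#' @param min_density_bp_per_snp maximum average inter-SNP span: a run needs
#'   at least one SNP per this many bp (default 50000).
#' @param max_gap_bp maximum gap between consecutive SNPs within a run.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50L, window_max_het = 2L,
                       window_max_missing = 2L, hit_rate_threshold = 0.05,
                       min_snps = 50L, min_length_bp = 1e5,
                       min_density_bp_per_snp = 5e4, max_gap_bp = 1e5) {
  stopifnot(window_snps > 0, min_snps > 0, min_length_bp > 0,
            hit_rate_threshold > 0, hit_rate_threshold <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 window_max_het = as.integer(window_max_het),
                 window_max_missing = as.integer(window_max_missing),
                 hit_rate_threshold = hit_rate_threshold,
                 min_snps = as.integer(min_snps),
                 min_length_bp = min_length_bp,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_gap_bp = max_gap_bp),
            class = "roh_params")
}

## Internal: per-SNP eligibility on one chromosome for one sample.
## dosages: integer vector (0/1/2/NA) in map order.
window_scan_chrom <- function(dosages, params) {
  m <- length(dosages)
  w <- params$window_snps
  if (m < w) return(rep(FALSE, m))
  het <- as.integer(!is.na(dosages) & dosages == 1L)
  mis <- as.integer(is.na(dosages))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  starts <- seq_len(m - w + 1L)
  pass <- (ch[starts + w] - ch[starts]) <= params$window_max_het &
    (cm[starts + w] - cm[starts]) <= params$window_max_missing
  # SNP j is contained in windows starting in [j-w+1, j] clipped to valid
  cp <- c(0L, cumsum(as.integer(pass)))
  j <- seq_len(m)
  lo <- pmax(j - w + 1L, 1L)
  hi <- pmin(j, m - w + 1L)
  n_pass <- cp[hi + 1L] - cp[lo]
  n_win <- hi - lo + 1L
  (n_pass / n_win) > params$hit_rate_threshold
}

#' Per-SNP ROH eligibility flags for one sample
#'
#' Runs the sliding-window scan on each chromosome and returns, per SNP,
#' whether its hit rate (share of passing windows among windows containing
#' it) exceeds the threshold. Chromosomes with fewer SNPs than one window
#' yield all-ineligible flags.
#'
#' @param sample_dosages integer vector of dosages in map order.
#' @param map marker map (`chrom`, `pos_bp`), sorted.
#' @param params a [roh_params()].
#' @return logical vector along the map.
#' @export
window_scan <- function(sample_dosages, map, params = roh_params()) {
  flags <- logical(nrow(map))
  for (chr in unique(map$chrom)) {
    sel <- which(map$chrom == chr)
    flags[sel] <- window_scan_chrom(sample_dosages[sel], params)
  }
  flags
}

## Internal: apply run-level filters to candidate runs given index bounds
## (list of c(from, to) into `sel`), positions pos, and emit segments.
runs_to_segments <- function(bounds, pos, params) {
  keep <- list()
  for (b in bounds) {
    from <- b[1]
    to <- b[2]
    # split at gaps > max_gap_bp
    if (to > from) {
      gaps <- diff(pos[from:to])
      cut <- which(gaps > params$max_gap_bp)
      starts <- c(from, from + cut)
      ends <- c(from + cut - 1L, to)
    } else {
      starts <- from
      ends <- to
    }
    for (s in seq_along(starts)) {
      n_snp <- ends[s] - starts[s] + 1L
      len <- pos[ends[s]] - pos[starts[s]] + 1
      if (n_snp >= params$min_snps && len >= params$min_length_bp &&
          n_snp / len >= 1 / params$min_density_bp_per_snp)
        keep[[length(keep) + 1L]] <-
          c(starts[s], ends[s], n_snp, len)
    }
  }
  keep
}

## Internal: maximal TRUE runs of a logical vector -> list of c(from, to)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mapply(function(s, e) c(s, e), starts[r$values], ends[r$values],
         SIMPLIFY = FALSE)
}

#' Detect runs of homozygosity (sliding-window method)
#'
#' Per sample and chromosome, SNPs eligible under [window_scan()] form
#' candidate runs; runs are trimmed so they start and end on homozygous
#' non-missing SNPs, split at gaps above `max_gap_bp`, and must satisfy the
#' run-level minimum SNP count, length and density. Interior heterozygotes
#' tolerated by the window allowances do not break a run (only window-level
#' caps apply, so a detected run can bridge occasional genotyping errors).
#' Segment coordinates are the positions of the first and last SNP of the
#' run.
#'
#' @param dataset a QC'd [genotype_dataset()].
#' @param params a [roh_params()].
#' @return data.frame of class `roh_set`: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`.
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  out <- list()
  map <- dataset$map
  for (i in seq_along(dataset$sample_ids)) {
    x <- dataset$dosage[i, ]
    for (chr in unique(map$chrom)) {
      sel <- which(map$chrom == chr)
      flags <- window_scan_chrom(x[sel], params)
      if (!any(flags)) next
      hom <- !is.na(x[sel]) & x[sel] != 1L
      bounds <- true_runs(flags)
      # trim run ends to homozygous non-missing SNPs
      bounds <- lapply(bounds, function(b) {
        from <- b[1]
        to <- b[2]
        while (from <= to && !hom[from]) from <- from + 1L
        while (to >= from && !hom[to]) to <- to - 1L
        if (from > to) NULL else c(from, to)
      })
      bounds <- Filter(Negate(is.null), bounds)
      segs <- runs_to_segments(bounds, map$pos_bp[sel], params)
      for (sg in segs)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = dataset$sample_ids[i], chrom = chr,
          start_bp = map$pos_bp[sel][sg[1]], end_bp = map$pos_bp[sel][sg[2]],
          n_snps = sg[3], length_bp = sg[4])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), length_bp = numeric(0))
  class(res) <- c("roh_set", "data.frame")
  res
}

#' Exhaustive ROH oracle
#'
#' Reference detector for testing: maximal runs of strictly homozygous,
#' non-missing genotypes, then the same run-level filters (gap split,
#' minimum SNPs / length / density) as [detect_roh()]. On clean data the
#' two agree segment for segment; on data with interior heterozygotes the
#' oracle splits runs that the windowed detector may bridge — that
#' difference is the point of the window allowances.
#'
#' @inheritParams detect_roh
#' @return an `roh_set` data.frame.
#' @export
detect_roh_oracle <- function(dataset, params = roh_params()) {
  out <- list()
  map <- dataset$map
  for (i in seq_along(dataset$sample_ids)) {
    x <- dataset$dosage[i, ]
    for (chr in unique(map$chrom)) {
      sel <- which(map$chrom == chr)
      hom <- !is.na(x[sel]) & x[sel] != 1L
      if (!any(hom)) next
      segs <- runs_to_segments(true_runs(hom), map$pos_bp[sel], params)
      for (sg in segs)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = dataset$sample_ids[i], chrom = chr,
          start_bp = map$pos_bp[sel][sg[1]], end_bp = map$pos_bp[sel][sg[2]],
          n_snps = sg[3], length_bp = sg[4])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), length_bp = numeric(0))
  class(res) <- c("roh_set", "data.frame")
  res
}

#' Genomic inbreeding from ROH coverage
#'
#' `F_ROH` per sample: total ROH length divided by the autosomal genome
#' length. By default the genome length is the sum over chromosomes of the
#' SNP-covered span (last minus first mapped position + 1) of the analyzed
#' map; a fixed constant can be supplied instead.
#'
#' @param rohset an `roh_set` from [detect_roh()].
#' @param dataset the dataset the ROH were called on (used for the default
#'   genome length and the sample list); optional if both
#'   `genome_length_bp` and `sample_ids` are given.
#' @param genome_length_bp override for the autosomal genome length.
#' @param sample_ids samples to report (zero-ROH samples get `F_ROH = 0`).
#' @return data.frame `sample_id`, `total_roh_bp`, `genome_bp`, `F_ROH`.
#' @export
froh <- function(rohset, dataset = NULL, genome_length_bp = NULL,
                 sample_ids = NULL) {
  if (is.null(genome_length_bp)) {
    if (is.null(dataset)) stop("need dataset or genome_length_bp")
    spans <- tapply(dataset$map$pos_bp, dataset$map$chrom,
                    function(p) max(p) - min(p) + 1)
    genome_length_bp <- sum(spans)
  }
  stopifnot(genome_length_bp > 0)
  if (is.null(sample_ids)) {
    if (!is.null(dataset)) sample_ids <- dataset$sample_ids
    else sample_ids <- unique(rohset$sample_id)
  }
  tot <- tapply(rohset$length_bp, rohset$sample_id, sum)
  total <- unname(tot[sample_ids])
  total[is.na(total)] <- 0
  if (any(total > genome_length_bp))
    stop("total ROH length exceeds genome length (overlapping segments?)")
  data.frame(sample_id = sample_ids, total_roh_bp = total,
             genome_bp = genome_length_bp, F_ROH = total / genome_length_bp)
}
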