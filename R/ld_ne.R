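#' Pairwise syntenic r-squared
#'
#' For every within-chromosome marker pair closer than `max_distance_bp`,
#' the squared Pearson correlation of the dosage vectors over
#' pairwise-complete samples (genotypic / composite LD — no phasing
#' required). Pairs involving a zero-variance marker are skipped.
#'
#' @param dataset a QC'd [genotype_dataset()] with sorted map.
#' @param max_distance_bp only pairs closer than this are computed.
#' @return data.frame `chrom`, `distance_bp`, `r2`.
#' @export
pairwise_r2 <- function(dataset, max_distance_bp = 1e6) {
  map <- dataset$map
  out <- vector("list", length(unique(map$chrom)))
  ci <- 0
  for (chr in unique(map$chrom)) {
    sel <- which(map$chrom == chr)
    if (length(sel) < 2) next
    pos <- map$pos_bp[sel]
    x <- dataset$dosage[, sel, drop = FALSE]
    keep <- apply(x, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
    keep[is.na(keep)] <- FALSE
    sel2 <- which(keep)
    if (length(sel2) < 2) next
    pos <- pos[sel2]
    x <- x[, sel2, drop = FALSE]
    suppressWarnings(
      cc <- stats::cor(x, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    ok <- d > 0 & d < max_distance_bp & !is.na(cc[pr])
    ci <- ci + 1
    out[[ci]] <- data.frame(chrom = rep(chr, sum(ok)),
                            distance_bp = d[ok], r2 = cc[pr][ok]^2)
  }
  if (ci == 0)
    return(data.frame(chrom = integer(0), distance_bp = numeric(0),
                      r2 = numeric(0)))
  do.call(rbind, out[seq_len(ci)])
}

#' Distance-binned LD decay
#'
#' Mean r-squared and pair count per physical-distance bin. Default bins run
#' 0 to 1 Mb in 20-kb steps. Empty bins are omitted.
#'
#' @param pairs output of [pairwise_r2()].
#' @param bin_edges increasing numeric vector of bin boundaries in bp; a
#'   pair with distance d falls in bin `[edge_i, edge_{i+1})`.
#' @return data.frame `bin_lo`, `bin_hi`, `mid_bp`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(pairs, bin_edges = seq(0, 1e6, by = 2e4)) {
  if (nrow(pairs) == 0) stop("empty pair table")
  bin <- findInterval(pairs$distance_bp, bin_edges,
                      rightmost.closed = FALSE)
  ok <- bin >= 1 & bin < length(bin_edges)
  bin <- bin[ok]
  r2 <- pairs$r2[ok]
  mean_r2 <- tapply(r2, bin, mean)
  n <- tapply(r2, bin, length)
  b <- as.integer(names(mean_r2))
  data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1],
             mid_bp = (bin_edges[b] + bin_edges[b + 1]) / 2,
             mean_r2 = as.numeric(mean_r2), n_pairs = as.integer(n))
}

#' Sved-equation Ne parameters
#'
#' Settings of the mapping from binned LD to effective population size:
#' expected r-squared at recombination distance c Morgans is approximately
#' `1 / (alpha + 4 N c)`, so `Ne = (1/(4c)) (1/r2_adj - alpha)` with
#' `r2_adj = mean r2 - 1/(beta n)` correcting for sample size; `t = 1/(2c)`
#' generations ago.
#'
#' @param bp_to_morgan physical-to-map conversion (default 1e-8, i.e.
#'   1 cM/Mb; a genome-average rate absent a recombination map).
#' @param alpha mutation adjustment (1 = none, 2 = mutation-adjusted).
#' @param beta sample-size-correction form: 1 for unphased genotypic
#'   correlations, 2 for phased haplotypes.
#' @return list of class `ne_params`.
#' @export
ne_params <- function(bp_to_morgan = 1e-8, alpha = 2, beta = 1) {
  stopifnot(bp_to_morgan > 0, alpha %in% c(1, 2, 2.2), beta %in% c(1, 2))
  structure(list(bp_to_morgan = bp_to_morgan, alpha = alpha, beta = beta),
            class = "ne_params")
}

#' Ne trajectory from binned LD decay
#'
#' Each distance bin maps to a time horizon `t = 1/(2 c)` generations ago
#' (c = bin midpoint in Morgans) and an effective size
#' `Ne = (1/(4c)) (1/r2_adj - alpha)`. Bins whose adjusted mean r-squared is
#' not positive, or that yield non-positive Ne, are dropped (and counted in
#' the `n_dropped` attribute).
#'
#' @param decay_table from [ld_decay()].
#' @param params an [ne_params()].
#' @param n_samples number of samples behind the r2 estimates (for the
#'   `1/(beta n)` correction).
#' @return data.frame `t_generations`, `Ne`, `mid_bp`, `mean_r2`, ordered by
#'   increasing t.
#' @export
estimate_ne <- function(decay_table, params = ne_params(), n_samples) {
  stopifnot(n_samples > 0)
  cM <- decay_table$mid_bp * params$bp_to_morgan
  r2adj <- decay_table$mean_r2 - 1 / (params$beta * n_samples)
  ne <- (1 / (4 * cM)) * (1 / r2adj - params$alpha)
  t <- round(1 / (2 * cM))
  ok <- r2adj > 0 & ne > 0 & is.finite(ne)
  out <- data.frame(t_generations = t[ok], Ne = ne[ok],
                    mid_bp = decay_table$mid_bp[ok],
                    mean_r2 = decay_table$mean_r2[ok])
  out <- out[order(out$t_generations), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}
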