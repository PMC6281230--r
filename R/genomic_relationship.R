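#' Allele frequencies
#'
#' Frequency of `allele2` per marker over non-missing calls.
#'
#' @param dataset a [genotype_dataset()].
#' @return data.frame with `marker_id`, `p` (allele2 frequency; `NA` when no
#'   calls), `n_calls`.
#' @export
allele_frequencies <- function(dataset) {
  if (nrow(dataset$map) == 0) stop("empty dataset")
  n_calls <- colSums(!is.na(dataset$dosage))
  p <- colSums(dataset$dosage, na.rm = TRUE) / (2 * n_calls)
  p[n_calls == 0] <- NA_real_
  data.frame(marker_id = dataset$map$marker_id, p = unname(p),
             n_calls = unname(n_calls))
}

#' Genomic relationship matrix (allele-frequency-scaled, per-locus)
#'
#' The estimator of Yang et al.: relationships are accumulated locus by
#' locus, each locus scaled by its own heterozygosity `2 p_k (1 - p_k)`
#' (in contrast to the VanRaden estimator, which scales the whole matrix by
#' one constant). Off-diagonals are
#' `g_ij = (1/m_ij) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))`
#' and diagonals
#' `g_ii = 1 + (1/m_i) * sum_k (x_ik^2 - (1 + 2 p_k) x_ik + 2 p_k^2) / (2 p_k (1 - p_k))`,
#' with sums restricted to loci non-missing for the pair (`m_ij`) or the
#' individual (`m_i`). Monomorphic loci (p of 0 or 1) carry no information
#' and are excluded.
#'
#' @param dataset a [genotype_dataset()].
#' @param freqs optional allele-frequency table from [allele_frequencies()];
#'   computed from the dataset itself when omitted (no external reference
#'   panel is assumed).
#' @return symmetric numeric matrix with sample ids as dimnames; attribute
#'   `n_loci_used` gives the count of polymorphic loci entering the sums.
#' @export
genomic_relationship_matrix <- function(dataset, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(dataset)
  p <- freqs$p
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("no polymorphic loci")
  x <- dataset$dosage[, use, drop = FALSE]
  p <- p[use]
  n <- nrow(x)
  het <- 2 * p * (1 - p)
  obs <- !is.na(x)
  xw <- sweep(x, 2, 2 * p)              # x - 2p (NA propagated)
  xw <- sweep(xw, 2, sqrt(het), "/")
  xw[!obs] <- 0
  num <- tcrossprod(xw)                  # sum_k w_ik w_jk over shared loci
  mobs <- tcrossprod(obs * 1)            # m_ij
  if (any(mobs == 0))
    stop("sample pair with zero shared genotyped loci")
  G <- num / mobs
  # diagonal: 1 + mean of (x^2 - (1+2p)x + 2p^2)/(2p(1-p))
  xs <- x
  term <- (xs * xs - sweep(xs, 2, 1 + 2 * p, FUN = "*") +
             matrix(2 * p^2, nrow = n, ncol = length(p), byrow = TRUE)) /
    matrix(het, nrow = n, ncol = length(p), byrow = TRUE)
  term[!obs] <- 0
  diag(G) <- 1 + rowSums(term) / rowSums(obs)
  dimnames(G) <- list(dataset$sample_ids, dataset$sample_ids)
  attr(G, "n_loci_used") <- sum(use)
  G
}

#' Identity-by-state distance matrix
#'
#' Per locus the shared-allele score is 2 for identical genotypes, 0 for
#' opposite homozygotes and 1 otherwise; the distance is the complement to
#' one of the IBS proportion, `D_ij = 1 - sum(s) / (2 L_ij)`, over loci
#' non-missing in both samples.
#'
#' @param dataset a [genotype_dataset()].
#' @return symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
ibs_distance_matrix <- function(dataset) {
  x <- dataset$dosage
  if (is.null(x) || ncol(x) == 0) stop("empty dataset")
  n <- nrow(x)
  obs <- !is.na(x)
  L <- tcrossprod(obs * 1)
  if (any(L == 0)) {
    bad <- which(L == 0, arr.ind = TRUE)[1, ]
    stop("no shared genotyped loci for pair ",
         dataset$sample_ids[bad[1]], " / ", dataset$sample_ids[bad[2]])
  }
  # s_ij(k) = 2 - |x_i - x_j|; sum over shared loci.
  # sum |x_i - x_j| decomposes over indicator matrices of each dosage class.
  i0 <- (obs & x == 0L) * 1
  i1 <- (obs & x == 1L) * 1
  i2 <- (obs & x == 2L) * 1
  absdiff <- tcrossprod(i0, i1) + tcrossprod(i1, i0) +
    tcrossprod(i1, i2) + tcrossprod(i2, i1) +
    2 * (tcrossprod(i0, i2) + tcrossprod(i2, i0))
  D <- absdiff / (2 * L)
  diag(D) <- 0
  dimnames(D) <- list(dataset$sample_ids, dataset$sample_ids)
  D
}

#' Correlation between two relationship matrices
#'
#' Pearson correlation between matched entries of two symmetric matrices
#' (e.g. genomic G vs pedigree A), either over the off-diagonal upper
#' triangle (default) or including the diagonal. Samples are matched by
#' label; both matrices are subset to the shared labels.
#'
#' @param G,A symmetric matrices with dimnames.
#' @param mode `"off_diagonal"` or `"all"`.
#' @return Pearson correlation (single number).
#' @export
matrix_correlation <- function(G, A, mode = c("off_diagonal", "all")) {
  mode <- match.arg(mode)
  shared <- intersect(rownames(G), rownames(A))
  if (length(shared) < 2) stop("fewer than 2 shared labels")
  G <- G[shared, shared]
  A <- A[shared, shared]
  sel <- upper.tri(G, diag = (mode == "all"))
  if (sum(sel) < 3) stop("fewer than 3 entries to correlate")
  stats::cor(G[sel], A[sel])
}
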