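#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds samples on the top
#' eigenvectors scaled by the square roots of their (positive) eigenvalues.
#' Delegates to `stats::cmdscale`, which implements exactly this scaling.
#' When fewer than `k` positive eigenvalues exist, fewer columns are
#' returned with a warning.
#'
#' @param distance_matrix symmetric matrix with zero diagonal.
#' @param k number of dimensions (default 3).
#' @return list with `coords` (n x k', column-centered), `eigenvalues`
#'   (all n, decreasing).
#' @export
classical_mds <- function(distance_matrix, k = 3) {
  stopifnot(isSymmetric(unname(distance_matrix)),
            all(abs(diag(distance_matrix)) < 1e-12))
  n <- nrow(distance_matrix)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(distance_matrix),
                    k = min(k, n - 1), eig = TRUE))
  npos <- sum(fit$eig > 1e-10)
  if (npos < k)
    warning("only ", npos, " positive eigenvalues; returning ",
            min(npos, ncol(fit$points)), " dimensions")
  coords <- fit$points[, seq_len(min(k, npos)), drop = FALSE]
  rownames(coords) <- rownames(distance_matrix)
  list(coords = coords, eigenvalues = sort(fit$eig, decreasing = TRUE))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion (via `ape::nj`); negative
#' branch lengths, an artifact of non-additive input, are clamped to zero
#' with the total deficit recorded in the `clamped_length` attribute.
#'
#' @param distance_matrix symmetric distance matrix (>= 3 taxa).
#' @param labels optional taxon labels (default: dimnames).
#' @return newick string (with a `phylo` attribute carrying the tree and
#'   `clamped_length` the clamped total).
#' @export
nj_tree <- function(distance_matrix, labels = NULL) {
  if (is.null(labels)) labels <- rownames(distance_matrix)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(distance_matrix)))
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (nrow(distance_matrix) < 3) stop("need at least 3 taxa")
  dm <- distance_matrix
  dimnames(dm) <- list(labels, labels)
  tree <- ape::nj(stats::as.dist(dm))
  deficit <- -sum(pmin(tree$edge.length, 0))
  tree$edge.length <- pmax(tree$edge.length, 0)
  nwk <- ape::write.tree(tree)
  attr(nwk, "phylo") <- tree
  attr(nwk, "clamped_length") <- deficit
  nwk
}

#' Breed-level mean distance matrix
#'
#' Averages between-sample distances per breed pair (diagonal zero), giving
#' the breed-level matrix used for between-breed trees.
#'
#' @param distance_matrix sample-level distance matrix.
#' @param breeds character vector of breed labels aligned to rows.
#' @return symmetric breed x breed matrix.
#' @export
breed_distance_matrix <- function(distance_matrix, breeds) {
  ub <- sort(unique(breeds))
  out <- matrix(0, length(ub), length(ub), dimnames = list(ub, ub))
  for (i in seq_along(ub)) for (j in seq_along(ub)) {
    if (i >= j) next
    block <- distance_matrix[breeds == ub[i], breeds == ub[j], drop = FALSE]
    out[i, j] <- out[j, i] <- mean(block)
  }
  out
}

#' Fit the admixture model by EM
#'
#' Maximizes the binomial admixture log-likelihood
#' `l = sum_il [ x_il log(pi_il) + (2 - x_il) log(1 - pi_il) ]`,
#' `pi_il = sum_k q_ik f_kl`, by plain EM (frappe-style multiplicative
#' updates) — the same model ADMIXTURE optimizes with quasi-Newton
#' acceleration; EM is slower per unit of convergence but monotone and
#' simple. Missing genotypes are skipped in all sums; `pi` is clipped to
#' `[1e-10, 1 - 1e-10]`. Multiple seeded restarts keep the best final
#' log-likelihood (ties broken by the lowest restart index).
#'
#' @param dataset a QC'd [genotype_dataset()].
#' @param K number of ancestral populations (>= 1).
#' @param seed RNG seed for the restarts' initializations.
#' @param tol stop when the log-likelihood gain per iteration falls below
#'   this.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random restarts.
#' @return list of class `admixture_result`: `K`, `Q` (n x K, rows sum to
#'   1), `P` (K x m in `[0,1]`), `loglik`, `loglik_trace`, `iterations`,
#'   `seed`.
#' @export
admixture_fit <- function(dataset, K, seed = 1, tol = 1e-4,
                          max_iter = 500, n_restarts = 3) {
  X <- dataset$dosage
  fit <- admixture_fit_matrix(X, K, seed = seed, tol = tol,
                              max_iter = max_iter, n_restarts = n_restarts)
  rownames(fit$Q) <- dataset$sample_ids
  colnames(fit$P) <- dataset$map$marker_id
  fit
}

## Matrix-level fit (used by CV on masked matrices)
admixture_fit_matrix <- function(X, K, seed = 1, tol = 1e-4,
                                 max_iter = 500, n_restarts = 3) {
  n <- nrow(X)
  m <- ncol(X)
  if (K > n) stop("K exceeds sample count")
  stopifnot(K >= 1)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0)) stop("sample with no observed genotypes")
  Xo <- X
  Xo[!obs] <- 0
  X2 <- 2 - X
  X2[!obs] <- 0
  Li <- rowSums(obs)
  clip <- function(v) pmin(pmax(v, 1e-10), 1 - 1e-10)
  loglik_of <- function(Q, P) {
    Pi <- clip(Q %*% P)
    sum(Xo * log(Pi) + X2 * log1p(-Pi))
  }
  if (K == 1) {
    # closed form: single population, P = observed allele frequencies
    P <- matrix(colSums(Xo) / (2 * colSums(obs)), nrow = 1)
    P[!is.finite(P)] <- 0.5
    Q <- matrix(1, n, 1)
    ll <- loglik_of(Q, P)
    return(structure(list(K = 1L, Q = Q, P = P, loglik = ll,
                          loglik_trace = ll, iterations = 0L, seed = seed),
                     class = "admixture_result"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
    ll <- loglik_of(Q, P)
    trace <- ll
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      Pi <- clip(Q %*% P)
      RA <- Xo / Pi
      RB <- X2 / (1 - Pi)
      # E+M in one sweep (multiplicative updates on the same Pi)
      A_num <- P * (crossprod(Q, RA))        # K x m: sum_i q f x a-part
      B_num <- (1 - P) * (crossprod(Q, RB))
      Qnew <- Q * ((RA %*% t(P)) + (RB %*% t(1 - P))) / (2 * Li)
      Qnew <- Qnew / rowSums(Qnew)
      Pnew <- A_num / (A_num + B_num)
      Pnew[!is.finite(Pnew)] <- 0.5
      Pnew <- clip(Pnew)
      Q <- Qnew
      P <- Pnew
      llnew <- loglik_of(Q, P)
      trace <- c(trace, llnew)
      if (llnew - ll < tol && it > 1) {
        ll <- llnew
        break
      }
      ll <- llnew
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(K = as.integer(K), Q = Q, P = P, loglik = ll,
                   loglik_trace = trace, iterations = it,
                   seed = seed + r - 1L)
    }
  }
  structure(best, class = "admixture_result")
}

#' Cross-validated choice of K for the admixture model
#'
#' Non-missing genotype entries are partitioned at random (seeded) into
#' `folds` folds; for each fold those entries are masked as missing, the
#' model is refit for every K on the masked data, and the prediction error
#' is the mean over masked entries of `(x - 2 * pi_hat)^2`. Every K sees
#' identical masks. The selected K minimizes the mean error across folds.
#'
#' @param dataset a [genotype_dataset()].
#' @param K_list integer vector of K values to evaluate.
#' @param folds number of folds (>= 2).
#' @param seed RNG seed (masking and restarts).
#' @param tol,max_iter,n_restarts passed to the fits.
#' @return list of class `cv_report`: `table` (data.frame K, cv_error),
#'   `selected_K`, `fold_errors` (K x folds matrix).
#' @export
admixture_cv <- function(dataset, K_list = 1:4, folds = 5, seed = 1,
                         tol = 1e-4, max_iter = 300, n_restarts = 1) {
  stopifnot(folds >= 2)
  X <- dataset$dosage
  obs_idx <- which(!is.na(X))
  set.seed(seed)
  fold_of <- sample(rep(seq_len(folds), length.out = length(obs_idx)))
  errs <- matrix(NA_real_, nrow = length(K_list), ncol = folds,
                 dimnames = list(paste0("K", K_list), NULL))
  for (f in seq_len(folds)) {
    masked <- obs_idx[fold_of == f]
    Xf <- X
    Xf[masked] <- NA
    # markers left with no observed entries cannot be predicted
    ok_marker <- colSums(!is.na(Xf)) > 0
    marker_of <- ((masked - 1) %/% nrow(X)) + 1
    drop_entries <- masked[marker_of %in% which(!ok_marker)]
    for (ki in seq_along(K_list)) {
      fit <- admixture_fit_matrix(Xf, K_list[ki], seed = seed + 100 * f,
                                  tol = tol, max_iter = max_iter,
                                  n_restarts = n_restarts)
      Pi <- fit$Q %*% fit$P
      eval_idx <- masked[!(masked %in% drop_entries)]
      errs[ki, f] <- mean((X[eval_idx] - 2 * Pi[eval_idx])^2)
    }
  }
  cv <- rowMeans(errs)
  tab <- data.frame(K = K_list, cv_error = unname(cv))
  structure(list(table = tab, selected_K = K_list[which.min(cv)],
                 fold_errors = errs),
            class = "cv_report")
}

#' Align admixture components to a reference
#'
#' Finds the column permutation of `Q` minimizing the root-mean-square
#' difference to `Q_ref` (label switching is inherent to mixture models).
#'
#' @param Q fitted ancestry matrix (n x K).
#' @param Q_ref reference ancestry matrix (n x K).
#' @return list `Q` (permuted), `perm`, `rmse`.
#' @export
align_q <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q))
  perms <- all_permutations(K)
  best <- NULL
  for (pm in perms) {
    r <- sqrt(mean((Q[, pm, drop = FALSE] - Q_ref)^2))
    if (is.null(best) || r < best$rmse)
      best <- list(Q = Q[, pm, drop = FALSE], perm = pm, rmse = r)
  }
  best
}

## Internal: all permutations of 1..k (k small)
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (s in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(s, k, after = pos - 1L)
  }
  out
}
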