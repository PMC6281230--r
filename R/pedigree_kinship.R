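#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A from a pedigree by
#' Henderson's tabular method, processing animals in topological order:
#' founders get `a_ii = 1`; for animal i with parents s and d,
#' `a_ij = (a_{j,s} + a_{j,d}) / 2` for previously processed j (missing
#' parents contribute 0) and `a_ii = 1 + a_{s,d} / 2`. Diagonal elements are
#' `1 + F_i` with `F_i` the inbreeding coefficient.
#'
#' @param ped a `pedigree_table` (see [pedigree_table()] / [read_pedigree()]).
#' @return symmetric matrix with animal ids as dimnames.
#' @export
additive_relationship_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(s)) rel <- rel + A[j, s]
      if (!is.na(d)) rel <- rel + A[j, d]
      rel <- rel / 2
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Pedigree inbreeding coefficients
#'
#' `F_i = A_ii - 1` from the numerator relationship matrix.
#'
#' @param ped a `pedigree_table`.
#' @return data.frame with `animal`, `F`; attributes `mean_F` and `sd_F`.
#' @export
pedigree_inbreeding <- function(ped) {
  A <- additive_relationship_matrix(ped)
  f <- diag(A) - 1
  out <- data.frame(animal = ped$animal, F = unname(f))
  attr(out, "mean_F") <- mean(f)
  attr(out, "sd_F") <- stats::sd(f)
  out
}

#' Generation numbers
#'
#' Generation of an animal is 0 for founders and `1 + max(parent
#' generations)` otherwise (maximum-generations-traced convention); with
#' `complete = TRUE` the alternative "complete generations" count
#' (`1 + min(parent generations)`, unknown parent counted as generation -1)
#' is returned instead.
#'
#' @param ped a `pedigree_table`.
#' @param complete use the complete-generations definition.
#' @param focal optional character vector of animal ids over which the
#'   summary mean depth is computed (e.g. the genotyped subset); defaults to
#'   all animals.
#' @return data.frame `animal`, `generation`; attribute `mean_depth`.
#' @export
generation_number <- function(ped, complete = FALSE, focal = NULL) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  gen <- integer(n)
  for (i in seq_len(n)) {
    gs <- if (is.na(si[i])) -1L else gen[si[i]]
    gd <- if (is.na(di[i])) -1L else gen[di[i]]
    if (is.na(si[i]) && is.na(di[i])) {
      gen[i] <- 0L
    } else {
      gen[i] <- 1L + if (complete) min(gs, gd) else max(gs, gd)
    }
  }
  gen <- pmax(gen, 0L)
  out <- data.frame(animal = ped$animal, generation = gen)
  if (is.null(focal)) focal <- ped$animal
  attr(out, "mean_depth") <- mean(gen[ped$animal %in% focal])
  out
}

#' Mean inbreeding per generation
#'
#' Groups animals by generation number and reports the mean inbreeding
#' coefficient and group size per generation.
#'
#' @param ped a `pedigree_table`.
#' @param complete passed to [generation_number()].
#' @return data.frame `generation`, `mean_F`, `n` (rows only for non-empty
#'   generations).
#' @export
per_generation_inbreeding <- function(ped, complete = FALSE) {
  f <- pedigree_inbreeding(ped)
  g <- generation_number(ped, complete = complete)
  agg <- stats::aggregate(f$F, by = list(generation = g$generation),
                          FUN = mean)
  cnt <- as.data.frame(table(g$generation), stringsAsFactors = FALSE)
  data.frame(generation = agg$generation, mean_F = agg$x,
             n = as.integer(cnt$Freq[match(agg$generation, cnt$Var1)]))
}
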