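#' Evenly spaced marker map
#'
#' Builds a marker map with `m` markers split evenly across `chromosomes`
#' chromosomes of `chrom_length_bp` bp, positions evenly spaced. Marker
#' ascertainment (the non-uniform spacing and MAF enrichment of real
#' arrays) is deliberately not modeled.
#'
#' @param m total marker count (divisible by `chromosomes`).
#' @param chromosomes number of autosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @return map data.frame as used by [genotype_dataset()].
#' @export
sim_map <- function(m, chromosomes = 38, chrom_length_bp = 1e8) {
  if (m %% chromosomes != 0)
    stop("m must be divisible across chromosomes")
  mc <- m %/% chromosomes
  pos <- round(seq(chrom_length_bp / (2 * mc), chrom_length_bp,
                   length.out = mc))
  data.frame(
    marker_id = paste0("snp", seq_len(m)),
    chrom = rep(seq_len(chromosomes), each = mc),
    pos_bp = as.integer(rep(pos, chromosomes)),
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
}

#' Simulate founder genotypes
#'
#' Per-marker allele frequencies are drawn from the chosen spectrum and
#' founder haplotypes are i.i.d. Bernoulli draws — founders are unrelated
#' and in linkage equilibrium.
#'
#' @param n number of diploid founders.
#' @param m marker count.
#' @param chromosomes number of chromosomes.
#' @param freq_dist `"uniform"` (range `freq_par[1]`-`freq_par[2]`) or
#'   `"beta"` (shape parameters `freq_par`).
#' @param freq_par parameters of the frequency distribution
#'   (default uniform on 0.05-0.5: a flat MAF spectrum as on a filtered
#'   genotyping array).
#' @param chrom_length_bp chromosome length.
#' @param seed RNG seed.
#' @return list: `dataset` (a [genotype_dataset()]), `haplotypes`
#'   (2n x m 0/1 matrix, rows 2i-1 and 2i belong to founder i), `p` (true
#'   allele2 frequencies).
#' @export
sim_founders <- function(n, m, chromosomes = 38,
                         freq_dist = c("uniform", "beta"),
                         freq_par = c(0.05, 0.5),
                         chrom_length_bp = 1e8, seed = 1) {
  freq_dist <- match.arg(freq_dist)
  set.seed(seed)
  p <- switch(freq_dist,
              uniform = stats::runif(m, freq_par[1], freq_par[2]),
              beta = stats::rbeta(m, freq_par[1], freq_par[2]))
  if (any(!is.finite(p))) stop("invalid frequency distribution parameters")
  hap <- matrix(stats::rbinom(2L * n * m, 1L, rep(p, each = 2L * n)),
                nrow = 2L * n, ncol = m)
  map <- sim_map(m, chromosomes, chrom_length_bp)
  dosage <- hap[seq(1, 2 * n, by = 2), , drop = FALSE] +
    hap[seq(2, 2 * n, by = 2), , drop = FALSE]
  ds <- genotype_dataset(dosage, map, paste0("F", seq_len(n)))
  list(dataset = ds, haplotypes = hap, p = p)
}

## Internal: one meiosis. alleles/labels: 2 x m matrices (the parent's two
## haplotypes); returns list(allele, label) vectors for the gamete.
## Haldane model: crossover count ~ Poisson(chromosome length in Morgans),
## positions uniform; independent random start phase per chromosome.
meiosis <- function(alleles, labels, chrom_index, pos_morgan_within) {
  m <- ncol(alleles)
  phase <- integer(m)
  for (chr in seq_along(chrom_index)) {
    sel <- chrom_index[[chr]]
    len <- pos_morgan_within[[chr]][length(sel)]
    k <- stats::rpois(1, len)
    start <- stats::rbinom(1, 1, 0.5)
    if (k == 0) {
      phase[sel] <- start
    } else {
      xo <- sort(stats::runif(k, 0, len))
      phase[sel] <- (start + findInterval(pos_morgan_within[[chr]], xo)) %% 2L
    }
  }
  row <- phase + 1L
  idx <- cbind(row, seq_len(m))
  list(allele = alleles[idx], label = labels[idx])
}

## Internal: per-chromosome marker indices and within-chromosome Morgan
## positions for a map.
map_geometry <- function(map, morgan_per_bp = 1e-8) {
  chroms <- unique(map$chrom)
  chrom_index <- lapply(chroms, function(ch) which(map$chrom == ch))
  pos_morgan <- lapply(chrom_index, function(sel)
    (map$pos_bp[sel] - map$pos_bp[sel[1]]) * morgan_per_bp)
  list(chrom_index = chrom_index, pos_morgan = pos_morgan)
}

#' Gene dropping down a pedigree
#'
#' Transmits founder haplotypes down the pedigree with Haldane-model
#' recombination (no interference; map distance 1 cM/Mb by default).
#' Founder-allele labels are tracked alongside alleles, so realized
#' autozygosity — the fraction of markers where an animal's two haplotypes
#' descend from the same founder haplotype — and the corresponding IBD
#' segments are recorded, at marker resolution.
#'
#' @param founders output of [sim_founders()]; its haplotype rows are
#'   assigned, in order, to the pedigree founders (animals with both
#'   parents unknown) in pedigree order.
#' @param ped a `pedigree_table`.
#' @param morgan_per_bp recombination rate (default 1e-8 = 1 cM/Mb).
#' @param seed RNG seed.
#' @return list: `dataset` (genotypes of all pedigree animals), `truth`
#'   (data.frame `animal`, `realized_F`), `ibd_segments` (data.frame
#'   `animal`, `chrom`, `start_bp`, `end_bp`, `n_snps`).
#' @export
gene_drop <- function(founders, ped, morgan_per_bp = 1e-8, seed = 1) {
  set.seed(seed)
  map <- founders$dataset$map
  m <- nrow(map)
  geom <- map_geometry(map, morgan_per_bp)
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  nf <- sum(is_founder)
  if (nrow(founders$haplotypes) < 2 * nf)
    stop("pedigree has ", nf, " founders but haplotypes for only ",
         nrow(founders$haplotypes) %/% 2)
  n <- nrow(ped)
  hapA <- matrix(0L, n, m)
  hapB <- matrix(0L, n, m)
  labA <- matrix(0L, n, m)
  labB <- matrix(0L, n, m)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  fcount <- 0
  for (i in seq_len(n)) {
    if (is_founder[i]) {
      fcount <- fcount + 1
      hapA[i, ] <- founders$haplotypes[2 * fcount - 1, ]
      hapB[i, ] <- founders$haplotypes[2 * fcount, ]
      labA[i, ] <- 2L * fcount - 1L
      labB[i, ] <- 2L * fcount
    } else {
      s <- idx[ped$sire[i]]
      d <- idx[ped$dam[i]]
      if (is.na(s) || is.na(d))
        stop("gene_drop requires both parents known for non-founders (",
             ped$animal[i], ")")
      gs <- meiosis(rbind(hapA[s, ], hapB[s, ]),
                    rbind(labA[s, ], labB[s, ]),
                    geom$chrom_index, geom$pos_morgan)
      gd <- meiosis(rbind(hapA[d, ], hapB[d, ]),
                    rbind(labA[d, ], labB[d, ]),
                    geom$chrom_index, geom$pos_morgan)
      hapA[i, ] <- gs$allele
      hapB[i, ] <- gd$allele
      labA[i, ] <- gs$label
      labB[i, ] <- gd$label
    }
  }
  dosage <- hapA + hapB
  ds <- genotype_dataset(dosage, map, ped$animal)
  ibd <- labA == labB
  truth <- data.frame(animal = ped$animal, realized_F = rowMeans(ibd))
  segs <- list()
  for (i in seq_len(n)) {
    if (!any(ibd[i, ])) next
    for (ch in seq_along(geom$chrom_index)) {
      sel <- geom$chrom_index[[ch]]
      for (b in true_runs(ibd[i, sel])) {
        segs[[length(segs) + 1L]] <- data.frame(
          animal = ped$animal[i], chrom = map$chrom[sel[1]],
          start_bp = map$pos_bp[sel[b[1]]], end_bp = map$pos_bp[sel[b[2]]],
          n_snps = b[2] - b[1] + 1L)
      }
    }
  }
  ibd_segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(animal = character(0), chrom = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0))
  list(dataset = ds, truth = truth, ibd_segments = ibd_segments)
}

#' Wright-Fisher population simulation
#'
#' Discrete non-overlapping generations of `N` (scalar, or a vector giving
#' the population size at each generation — e.g. a bottleneck) randomly
#' mating diploids; each offspring draws two parents at random and receives
#' recombinant gametes (Haldane model). No mutation: array SNPs are
#' pre-ascertained standing variation, initialized from `init_freq`.
#' Markers fixed by drift are dropped from the emitted sample.
#'
#' @param N population size per generation, recycled to `generations`.
#' @param generations number of generations to run (a common burn-in for
#'   equilibrium LD is 4N).
#' @param n_sample diploids sampled from the final generation.
#' @param m marker count.
#' @param chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length.
#' @param init_freq initial allele-frequency range (uniform).
#' @param morgan_per_bp recombination rate.
#' @param seed RNG seed.
#' @return list: `dataset` (sampled genotypes, monomorphic markers
#'   removed), `haplotypes` (the sampled individuals' haplotypes, two
#'   consecutive rows per diploid — usable as founder haplotypes for
#'   [gene_drop()], giving pedigree founders a drifted, LD-bearing
#'   background), `truth` (list with `N_history`, `n_polymorphic`,
#'   `n_fixed`).
#' @export
sim_wright_fisher <- function(N, generations, n_sample, m,
                              chromosomes = 20, chrom_length_bp = 1e8,
                              init_freq = c(0.05, 0.95),
                              morgan_per_bp = 1e-8, seed = 1) {
  set.seed(seed)
  stopifnot(all(N >= 2), n_sample >= 1)
  Nh <- rep_len(N, generations)
  map <- sim_map(m, chromosomes, chrom_length_bp)
  geom <- map_geometry(map, morgan_per_bp)
  p0 <- stats::runif(m, init_freq[1], init_freq[2])
  N0 <- Nh[1]
  # haplotypes held markers x haplotypes for column-major vector tricks
  hap <- matrix(stats::rbinom(2L * N0 * m, 1L, p0), nrow = m,
                ncol = 2L * N0)
  # per-marker switch probability to the previous marker's phase:
  # r = (1 - exp(-2 d)) / 2 under Haldane (independent across intervals),
  # and 1/2 at each chromosome start (random starting phase)
  r <- numeric(m)
  for (ch in seq_along(geom$chrom_index)) {
    sel <- geom$chrom_index[[ch]]
    d <- diff(geom$pos_morgan[[ch]])
    r[sel] <- c(0.5, (1 - exp(-2 * d)) / 2)
  }
  cur_N <- N0
  for (g in seq_len(generations)) {
    new_N <- Nh[g]
    ng <- 2L * new_N
    par <- sample.int(cur_N, ng, replace = TRUE)  # parent per gamete
    # phase per gamete: cumulative switch count mod 2 down each column
    sw <- matrix(stats::rbinom(m * ng, 1L, r), nrow = m, ncol = ng)
    cs <- cumsum(as.vector(sw))
    offs <- rep(c(0, cs[m * seq_len(ng - 1L)]), each = m)
    phase <- matrix((cs - offs) %% 2L, nrow = m, ncol = ng)
    hA <- hap[, 2L * par - 1L, drop = FALSE]
    hB <- hap[, 2L * par, drop = FALSE]
    hap <- hA + phase * (hB - hA)
    cur_N <- new_N
  }
  take <- sample.int(cur_N, min(n_sample, cur_N))
  dosage <- t(hap[, 2 * take - 1, drop = FALSE] +
                hap[, 2 * take, drop = FALSE])
  freq <- rowMeans(hap) # population frequency at the end
  poly <- freq > 0 & freq < 1
  if (!any(poly))
    stop("all markers fixed by drift; shorten the run or add markers")
  ds <- genotype_dataset(dosage[, poly, drop = FALSE],
                         map[poly, , drop = FALSE],
                         paste0("S", seq_along(take)))
  haps <- t(hap[poly, as.vector(rbind(2 * take - 1, 2 * take)),
                drop = FALSE])
  list(dataset = ds, haplotypes = haps,
       truth = list(N_history = Nh, n_polymorphic = sum(poly),
                    n_fixed = sum(!poly)))
}

#' Balding-Nichols admixture panel
#'
#' Ancestral allele frequencies uniform on 0.05-0.95; population
#' frequencies Beta-distributed around them with spread set by `fst`
#' (`Beta(p (1-F)/F, (1-p)(1-F)/F)`); individual ancestries Dirichlet;
#' dosages binomial on the individual's mixed frequency. Truth stores the
#' Q and P that generated the data.
#'
#' @param K ancestral populations (>= 2).
#' @param n samples.
#' @param m markers.
#' @param fst differentiation among ancestral populations, in (0, 1).
#' @param dirichlet_alpha Dirichlet concentration (scalar or length-K);
#'   small values give near-unadmixed individuals.
#' @param chromosomes,chrom_length_bp map geometry.
#' @param seed RNG seed.
#' @return list: `dataset`, `truth` (list `Q` (n x K), `P` (K x m)).
#' @export
sim_admixture <- function(K, n, m, fst = 0.1, dirichlet_alpha = 0.5,
                          chromosomes = 10, chrom_length_bp = 1e8,
                          seed = 1) {
  stopifnot(K >= 2, fst > 0, fst < 1, all(dirichlet_alpha > 0))
  set.seed(seed)
  alpha <- rep_len(dirichlet_alpha, K)
  p_anc <- stats::runif(m, 0.05, 0.95)
  sh1 <- p_anc * (1 - fst) / fst
  sh2 <- (1 - p_anc) * (1 - fst) / fst
  P <- matrix(0, K, m)
  for (k in seq_len(K)) P[k, ] <- stats::rbeta(m, sh1, sh2)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  Q <- g / rowSums(g)
  Pi <- Q %*% P
  dosage <- matrix(stats::rbinom(n * m, 2L, Pi), n, m)
  ds <- genotype_dataset(dosage, sim_map(m, chromosomes, chrom_length_bp),
                         paste0("I", seq_len(n)))
  list(dataset = ds, truth = list(Q = Q, P = P))
}

#' Multi-breed panel with unadmixed membership
#'
#' Balding-Nichols population frequencies as in [sim_admixture()], but each
#' sample belongs wholly to one breed (Q rows at the simplex vertices) and a
#' `breed` metadata column is attached — the substrate for breed-level
#' distance, MDS and tree analyses.
#'
#' @param n_per_breed samples per breed (scalar or length-`breeds` vector).
#' @param breeds number of breeds.
#' @param m markers.
#' @param fst between-breed differentiation.
#' @param chromosomes,chrom_length_bp map geometry.
#' @param seed RNG seed.
#' @return list: `dataset` (with `breed` metadata), `truth` (`P`, `breed`).
#' @export
sim_breed_panel <- function(n_per_breed, breeds = 3, m = 2000, fst = 0.1,
                            chromosomes = 10, chrom_length_bp = 1e8,
                            seed = 1) {
  set.seed(seed)
  npb <- rep_len(n_per_breed, breeds)
  n <- sum(npb)
  p_anc <- stats::runif(m, 0.05, 0.95)
  sh1 <- p_anc * (1 - fst) / fst
  sh2 <- (1 - p_anc) * (1 - fst) / fst
  P <- matrix(0, breeds, m)
  for (k in seq_len(breeds)) P[k, ] <- stats::rbeta(m, sh1, sh2)
  breed <- rep(seq_len(breeds), npb)
  Pi <- P[breed, , drop = FALSE]
  dosage <- matrix(stats::rbinom(n * m, 2L, Pi), n, m)
  meta <- data.frame(breed = paste0("B", breed))
  ds <- genotype_dataset(dosage, sim_map(m, chromosomes, chrom_length_bp),
                         paste0("I", seq_len(n)), metadata = meta)
  list(dataset = ds, truth = list(P = P, breed = meta$breed))
}

#' Plant homozygous segments into a genotype background
#'
#' Rebuilds the dosage matrix of `dataset`: outside the listed segments
#' genotypes are drawn at Hardy-Weinberg from each marker's allele
#' frequency (or all-heterozygous with `background = "het"`, which gives
#' clean segment boundaries for detector-vs-oracle comparisons); inside
#' each listed segment the sample is homozygous, the allele drawn per
#' marker by its frequency. Independent per-SNP flips to heterozygote at
#' `het_error_rate` inside segments emulate genotyping error. Overlapping
#' segments for the same sample are merged with a warning.
#'
#' @param dataset a [genotype_dataset()] supplying map and samples; its
#'   allele frequencies (or 0.5 where undefined) set the background.
#' @param segments data.frame `sample_id`, `chrom`, `start_bp`, `end_bp`.
#' @param het_error_rate per-SNP heterozygote-error probability inside
#'   segments.
#' @param background `"hw"` (Hardy-Weinberg) or `"het"` (all
#'   heterozygous).
#' @param seed RNG seed.
#' @return list: `dataset` (new dosages), `truth` (merged planted
#'   segments).
#' @export
plant_roh <- function(dataset, segments, het_error_rate = 0,
                      background = c("hw", "het"), seed = 1) {
  background <- match.arg(background)
  set.seed(seed)
  map <- dataset$map
  n <- length(dataset$sample_ids)
  m <- nrow(map)
  p <- allele_frequencies(dataset)$p
  p[is.na(p)] <- 0.5
  dosage <- if (background == "hw") {
    matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  } else {
    matrix(1L, n, m)
  }
  merged <- list()
  if (nrow(segments)) {
    for (sid in unique(segments$sample_id)) {
      i <- match(sid, dataset$sample_ids)
      if (is.na(i)) stop("unknown sample in segments: ", sid)
      ss <- segments[segments$sample_id == sid, , drop = FALSE]
      for (ch in unique(ss$chrom)) {
        sc <- ss[ss$chrom == ch, , drop = FALSE]
        sc <- sc[order(sc$start_bp), , drop = FALSE]
        if (any(sc$start_bp > sc$end_bp)) stop("segment start > end")
        if (max(sc$end_bp) > max(map$pos_bp[map$chrom == ch]) ||
            min(sc$start_bp) < min(map$pos_bp[map$chrom == ch]))
          stop("segment outside map bounds on chromosome ", ch)
        # merge overlaps
        out <- sc[1, , drop = FALSE]
        overlapped <- FALSE
        for (r in seq_len(nrow(sc))[-1]) {
          if (sc$start_bp[r] <= out$end_bp[nrow(out)]) {
            out$end_bp[nrow(out)] <- max(out$end_bp[nrow(out)],
                                         sc$end_bp[r])
            overlapped <- TRUE
          } else out <- rbind(out, sc[r, , drop = FALSE])
        }
        if (overlapped) warning("overlapping planted segments merged")
        for (r in seq_len(nrow(out))) {
          sel <- which(map$chrom == ch & map$pos_bp >= out$start_bp[r] &
                         map$pos_bp <= out$end_bp[r])
          hom <- 2L * stats::rbinom(length(sel), 1L, p[sel])
          err <- stats::rbinom(length(sel), 1L, het_error_rate) == 1L
          hom[err] <- 1L
          dosage[i, sel] <- hom
        }
        merged[[length(merged) + 1L]] <- out
      }
    }
  }
  truth <- if (length(merged)) do.call(rbind, merged) else
    segments[0, , drop = FALSE]
  ds <- genotype_dataset(dosage, map, dataset$sample_ids,
                         metadata = dataset$metadata)
  list(dataset = ds, truth = truth)
}
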