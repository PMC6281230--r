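# Small in-code fixtures shared across test files.

# dataset from an explicit dosage matrix on one chromosome, evenly spaced
toy_dataset <- function(dosage, spacing_bp = 1e5, chrom = 1L) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  map <- data.frame(marker_id = paste0("m", seq_len(m)),
                    chrom = chrom,
                    pos_bp = as.integer(seq_len(m) * spacing_bp),
                    allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  genotype_dataset(dosage, map,
                   paste0("s", seq_len(nrow(dosage))))
}

# founders 1,2; full sibs 3,4; their offspring 5 (F_5 = 0.25)
full_sib_pedigree <- function() {
  pedigree_table(c("1", "2", "3", "4", "5"),
                 c(NA, NA, "1", "1", "3"),
                 c(NA, NA, "2", "2", "4"))
}

# random valid pedigree: nf founders then no offspring of later generations
random_pedigree <- function(n, nf = 5, seed = 1) {
  set.seed(seed)
  animal <- as.character(seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    sire[i] <- as.character(sample.int(i - 1L, 1))
    dam[i] <- as.character(sample.int(i - 1L, 1))
  }
  pedigree_table(animal, sire, dam)
}

# Wright path-counting inbreeding for tiny pedigrees (independent oracle):
# F_i = sum over common-ancestor paths (1/2)^(L+1) (1 + F_A).
wright_f <- function(ped, id) {
  idx <- match(id, ped$animal)
  s <- ped$sire[idx]
  d <- ped$dam[idx]
  if (is.na(s) || is.na(d)) return(0)
  # enumerate ancestor paths from each parent (lists of ids up to founders)
  paths_up <- function(a) {
    i <- match(a, ped$animal)
    out <- list(a)
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p))
        out <- c(out, lapply(paths_up(p), function(pp) c(a, pp)))
    }
    out
  }
  ps <- paths_up(s)
  pd <- paths_up(d)
  f <- 0
  for (p1 in ps) for (p2 in pd) {
    anc <- p1[length(p1)]
    if (anc != p2[length(p2)]) next
    # paths must share ONLY the common ancestor
    if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0) next
    L <- (length(p1) - 1) + (length(p2) - 1)
    f <- f + 0.5^(L + 1) * (1 + wright_f(ped, anc))
  }
  f
}

# Planted-ROH fixture on a heterozygous background (clean boundaries).
# Segments are placed one per block with wide het margins: stretches of
# fewer than ~5 consecutive hets between homozygous runs can legitimately
# be bridged by the windowed detector (2 hets allowed per 50-SNP window),
# so separation is part of what "clean planted data" means.
roh_fixture <- function(n_samples = 2, m = 1200, spacing_bp = 5e3,
                        n_segments = 2, seed = 1) {
  set.seed(seed)
  base <- toy_dataset(matrix(1L, n_samples, m), spacing_bp = spacing_bp)
  pos <- base$map$pos_bp
  block <- m %/% n_segments
  segs <- list()
  for (i in seq_len(n_samples)) {
    for (b in seq_len(n_segments)) {
      len <- sample(100:250, 1)
      lo <- (b - 1L) * block + 20L
      hi <- b * block - 20L - len
      s <- sample(lo:hi, 1)
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = paste0("s", i), chrom = 1L,
        start_bp = pos[s], end_bp = pos[s + len])
    }
  }
  segments <- do.call(rbind, segs)
  plant_roh(base, segments, background = "het", seed = seed + 1000)
}
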