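#' Construct a genotype dataset
#'
#' The central container of the package: a samples x markers dosage matrix
#' (counts of `allele2`, values 0/1/2 or `NA` for missing) together with the
#' marker map and per-sample metadata.
#'
#' @param dosage integer matrix, samples in rows, markers in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos_bp`,
#'   `allele1`, `allele2`. `chrom` is an integer code (1-38 are canine
#'   autosomes; anything else is treated as non-autosomal by QC). `pos_bp`
#'   is 1-based.
#' @param sample_ids character vector of unique sample identifiers.
#' @param metadata optional data.frame of per-sample annotations (e.g. a
#'   `breed` column, `sex`); carried along, never interpreted by the core
#'   computations.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosage, map, sample_ids, metadata = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(map) != ncol(dosage))
    stop("map has ", nrow(map), " markers but dosage has ", ncol(dosage),
         " columns")
  if (length(sample_ids) != nrow(dosage))
    stop("sample_ids length does not match dosage rows")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (any(map$pos_bp < 1, na.rm = TRUE))
    stop("positions must be >= 1 (1-based coordinates)")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- map$marker_id
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if (nrow(metadata) != length(sample_ids))
      stop("metadata rows do not match samples")
  }
  structure(
    list(dosage = dosage, map = map,
         sample_ids = as.character(sample_ids), metadata = metadata),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$sample_ids), "samples x",
      nrow(x$map), "markers on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(length(x$sample_ids), nrow(x$map))

## Internal: sort markers by (chrom, pos) and check strict position ordering
sort_map <- function(dataset) {
  o <- order(dataset$map$chrom, dataset$map$pos_bp)
  dataset$map <- dataset$map[o, , drop = FALSE]
  rownames(dataset$map) <- NULL
  dataset$dosage <- dataset$dosage[, o, drop = FALSE]
  for (chr in unique(dataset$map$chrom)) {
    p <- dataset$map$pos_bp[dataset$map$chrom == chr]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", chr)
  }
  dataset
}

#' Read PLINK text genotypes (.ped / .map)
#'
#' Genotypes are recoded to dosages of `allele2`. The .map format carries no
#' allele labels, so orientation must be derived from the genotypes
#' themselves: by default `allele2` is the alphabetically later of the two
#' alleles observed at the marker (a deterministic, sample-order-independent
#' rule under which write/read round trips are exact for polymorphic
#' markers); with `recode_by_frequency = TRUE` the dataset is subsequently
#' re-oriented so `allele2` is the minor allele. The PLINK missing genotype
#' `0 0` becomes `NA`. A marker where only one allele is observed gets that
#' allele as `allele1` and dosage 0 (the orientation of a monomorphic marker
#' is unrecoverable from a .ped file).
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param recode_by_frequency if `TRUE`, orient each marker so that `allele2`
#'   is the minor allele on this dataset.
#' @return a [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path, recode_by_frequency = FALSE) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4) stop(".map needs 4 columns (chrom id cm pos)")
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  g1 <- matrix(NA_character_, nrow = n, ncol = m)
  g2 <- matrix(NA_character_, nrow = n, ncol = m)
  ids <- character(n)
  meta <- data.frame(fid = character(n), pid = character(n),
                     mid = character(n), sex = character(n),
                     phen = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("ragged .ped line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(f))
    ids[i] <- f[2]
    meta[i, ] <- f[c(1, 3, 4, 5, 6)]
    g1[i, ] <- f[seq(7, by = 2, length.out = m)]
    g2[i, ] <- f[seq(8, by = 2, length.out = m)]
  }
  a1 <- rep("0", m)
  a2 <- rep("0", m)
  dosage <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in seq_len(m)) {
    al <- c(g1[, k], g2[, k])
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2)
      stop("more than 2 distinct alleles at marker ", map_raw[k, 2], ": ",
           paste(obs, collapse = "/"))
    if (length(obs) >= 1) a1[k] <- obs[1]
    if (length(obs) == 2) a2[k] <- obs[2]
    miss <- g1[, k] == "0" | g2[, k] == "0"
    d <- (g1[, k] == a2[k]) + (g2[, k] == a2[k])
    d[miss] <- NA_integer_
    dosage[, k] <- as.integer(d)
  }
  map <- data.frame(marker_id = map_raw[, 2],
                    chrom = suppressWarnings(as.integer(map_raw[, 1])),
                    pos_bp = as.integer(map_raw[, 4]),
                    allele1 = a1, allele2 = a2,
                    stringsAsFactors = FALSE)
  map$chrom[is.na(map$chrom)] <- -1L  # non-numeric codes -> non-autosomal
  ds <- genotype_dataset(dosage, map, ids, metadata = meta)
  if (recode_by_frequency) ds <- recode_minor(ds)
  sort_map(ds)
}

#' Orient markers so allele2 is the minor allele
#'
#' Flips dosage (x -> 2 - x) and swaps allele labels at markers where the
#' `allele2` frequency exceeds 0.5 on this dataset. All downstream formulas
#' are symmetric in p vs 1-p; a fixed orientation just makes outputs
#' reproducible.
#' @param dataset a [genotype_dataset()].
#' @return the re-oriented dataset.
#' @export
recode_minor <- function(dataset) {
  p <- allele_frequencies(dataset)$p
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    dataset$dosage[, flip] <- 2L - dataset$dosage[, flip]
    tmp <- dataset$map$allele1[flip]
    dataset$map$allele1[flip] <- dataset$map$allele2[flip]
    dataset$map$allele2[flip] <- tmp
  }
  dataset
}

#' Read PLINK-1 binary genotypes (.bed / .bim / .fam)
#'
#' Expects the SNP-major PLINK-1 layout: magic bytes `0x6C 0x1B`, mode byte
#' `0x01`, then `ceiling(n/4)` bytes per marker. Two-bit codes (read from the
#' low bits of each byte upward) decode as 00 = homozygous allele1,
#' 01 = missing, 10 = heterozygous, 11 = homozygous allele2.
#'
#' @param bed_path,bim_path,fam_path file paths.
#' @return a [genotype_dataset()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  for (pth in c(bed_path, bim_path, fam_path))
    if (!file.exists(pth)) stop("no such file: ", pth)
  read_cols <- function(path, ncol) {
    if (length(readLines(path, n = 1)) == 0)
      return(as.data.frame(matrix(character(0), 0, ncol),
                           stringsAsFactors = FALSE))
    utils::read.table(path, header = FALSE, colClasses = "character")
  }
  bim <- read_cols(bim_path, 6)
  fam <- read_cols(fam_path, 6)
  m <- nrow(bim)
  n <- nrow(fam)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK-1 .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed (mode byte 0x01) is supported")
  bpm <- ceiling(n / 4)  # bytes per marker block
  if (length(raw) - 3 != bpm * m)
    stop(".bed truncated: expected ", bpm * m, " data bytes, found ",
         length(raw) - 3)
  body <- raw[-(1:3)]
  # decode all bytes to 4 two-bit codes (low bits first)
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  # codes is 4 x (bpm*m); reshape per marker and drop padding bits
  lut <- c(0L, NA_integer_, 1L, 2L)  # 00, 01, 10, 11
  dim(codes) <- c(4L * bpm, m)
  dec <- matrix(lut[codes + 1L], nrow = 4L * bpm, ncol = m)
  dosage <- dec[seq_len(n), , drop = FALSE]  # samples x markers
  map <- data.frame(marker_id = bim[, 2],
                    chrom = suppressWarnings(as.integer(bim[, 1])),
                    pos_bp = as.integer(bim[, 4]),
                    allele1 = bim[, 5], allele2 = bim[, 6],
                    stringsAsFactors = FALSE)
  map$chrom[is.na(map$chrom)] <- -1L
  meta <- data.frame(fid = fam[, 1], pid = fam[, 3], mid = fam[, 4],
                     sex = fam[, 5], phen = fam[, 6],
                     stringsAsFactors = FALSE)
  sort_map(genotype_dataset(dosage, map, fam[, 2], metadata = meta))
}

#' Write genotypes in PLINK text or binary format
#'
#' Emits `<prefix>.ped` + `<prefix>.map`, or `<prefix>.bed` + `.bim` + `.fam`.
#' Round-trips through the matching reader reproduce the dosage matrix
#' exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix.
#' @param format `"text"` or `"binary"`.
#' @return invisibly, the character vector of files written.
#' @export
write_genotypes <- function(dataset, prefix, format = c("text", "binary")) {
  format <- match.arg(format)
  map <- dataset$map
  n <- length(dataset$sample_ids)
  m <- nrow(map)
  meta <- dataset$metadata
  fid <- if (!is.null(meta$fid)) meta$fid else dataset$sample_ids
  pid <- if (!is.null(meta$pid)) meta$pid else rep("0", n)
  mid <- if (!is.null(meta$mid)) meta$mid else rep("0", n)
  sex <- if (!is.null(meta$sex)) meta$sex else rep("0", n)
  phen <- if (!is.null(meta$phen)) meta$phen else rep("-9", n)
  a1 <- map$allele1
  a2 <- map$allele2
  a1[is.na(a1) | a1 == "0"] <- "A"
  a2[is.na(a2) | a2 == "0"] <- "B"
  if (format == "text") {
    ped_path <- paste0(prefix, ".ped")
    map_path <- paste0(prefix, ".map")
    utils::write.table(
      data.frame(map$chrom, map$marker_id, rep(0, m), map$pos_bp),
      map_path, quote = FALSE, row.names = FALSE, col.names = FALSE,
      sep = "\t")
    con <- file(ped_path, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      x <- dataset$dosage[i, ]
      g1 <- ifelse(is.na(x), "0", ifelse(x >= 1, a2, a1))
      g2 <- ifelse(is.na(x), "0", ifelse(x == 2, a2, a1))
      cat(paste(c(fid[i], dataset$sample_ids[i], pid[i], mid[i], sex[i],
                  phen[i], as.vector(rbind(g1, g2))), collapse = " "),
          "\n", sep = "", file = con)
    }
    invisible(c(ped_path, map_path))
  } else {
    bed_path <- paste0(prefix, ".bed")
    bim_path <- paste0(prefix, ".bim")
    fam_path <- paste0(prefix, ".fam")
    utils::write.table(
      data.frame(map$chrom, map$marker_id, rep(0, m), map$pos_bp, a1, a2),
      bim_path, quote = FALSE, row.names = FALSE, col.names = FALSE,
      sep = "\t")
    utils::write.table(
      data.frame(fid, dataset$sample_ids, pid, mid, sex, phen),
      fam_path, quote = FALSE, row.names = FALSE, col.names = FALSE,
      sep = "\t")
    bpm <- ceiling(n / 4)
    # dosage -> 2-bit codes: 0->00, NA->01, 1->10, 2->11
    enc <- matrix(0L, nrow = 4 * bpm, ncol = m)
    x <- t(dataset$dosage)            # markers x samples
    code <- matrix(0L, nrow = m, ncol = n)
    code[is.na(x)] <- 1L
    code[!is.na(x) & x == 1L] <- 2L
    code[!is.na(x) & x == 2L] <- 3L
    enc[seq_len(n), ] <- t(code)
    bytes <- enc[seq(1, 4 * bpm, by = 4), , drop = FALSE] +
      4L * enc[seq(2, 4 * bpm, by = 4), , drop = FALSE] +
      16L * enc[seq(3, 4 * bpm, by = 4), , drop = FALSE] +
      64L * enc[seq(4, 4 * bpm, by = 4), , drop = FALSE]
    con <- file(bed_path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(as.vector(bytes)), con)
    invisible(c(bed_path, bim_path, fam_path))
  }
}

#' Read a pedigree table
#'
#' Reads a delimited file with animal / sire / dam columns (header optional;
#' detected when the first row's columns are not unique ids referenced
#' elsewhere, or explicitly via `header`). Unknown parents (`0`, `NA`, `""`,
#' `"."`) are normalized to `NA`. The returned table is topologically sorted
#' so parents precede offspring.
#'
#' @param path file path (whitespace, comma or tab separated).
#' @param header logical; does the file carry a header row?
#' @param unknown codes to treat as "parent unknown".
#' @return a `pedigree_table`: data.frame with columns `animal`, `sire`,
#'   `dam` (character, `NA` for unknown parents).
#' @export
read_pedigree <- function(path, header = FALSE,
                          unknown = c("0", "", ".", "NA")) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = header, sep = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) {
    tab <- utils::read.table(path, header = header, sep = ",",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 3) stop("pedigree needs >= 3 columns (animal sire dam)")
  pedigree_table(tab[, 1], tab[, 2], tab[, 3], unknown = unknown)
}

#' Construct and validate a pedigree table
#'
#' @param animal,sire,dam character vectors of ids; `unknown` codes and `NA`
#'   mark missing parents.
#' @param unknown codes normalized to `NA`.
#' @return topologically sorted `pedigree_table` (parents precede offspring).
#' @export
pedigree_table <- function(animal, sire, dam,
                           unknown = c("0", "", ".", "NA")) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[sire %in% unknown] <- NA
  dam[dam %in% unknown] <- NA
  if (anyDuplicated(animal))
    stop("duplicate animal id: ", animal[duplicated(animal)][1])
  # parents that never appear as animals become implicit founders
  parents <- setdiff(stats::na.omit(unique(c(sire, dam))), animal)
  if (length(parents)) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- unname(idx[sire])
  di <- unname(idx[dam])
  # Kahn topological sort; cycle detection with an offending chain
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg2[ch] <- indeg2[ch] - 1L
      if (indeg2[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n) {
    stuck <- setdiff(seq_len(n), order_out)
    # walk parent links among stuck nodes to exhibit a cycle
    chain <- stuck[1]
    repeat {
      v <- chain[length(chain)]
      p <- c(si[v], di[v])
      p <- p[!is.na(p) & p %in% stuck][1]
      if (p %in% chain) {
        chain <- c(chain, p)
        break
      }
      chain <- c(chain, p)
    }
    stop("pedigree contains a cycle: ",
         paste(animal[chain], collapse = " -> "))
  }
  out <- data.frame(animal = animal[order_out],
                    sire = sire[order_out], dam = dam[order_out],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pedigree_table", "data.frame")
  out
}
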