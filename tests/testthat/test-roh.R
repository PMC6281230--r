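test_that("window pass/fail follows the het and missing allowances", {
  # fully homozygous chromosome: every SNP eligible
  ds <- toy_dataset(matrix(0L, 1, 200), spacing_bp = 5e3)
  expect_true(all(window_scan(ds$dosage[1, ], ds$map)))
  # 3 hets inside every window spanning them -> those windows fail;
  # an isolated het keeps everything eligible (1 <= 2)
  x <- rep(0L, 200)
  x[100] <- 1L
  expect_true(all(window_scan(x, ds$map)))
  x[c(100, 101, 102)] <- 1L
  flags <- window_scan(x, ds$map)
  expect_false(flags[101])        # middle het: all its windows have 3 hets
  # missing counts against its own allowance
  y <- rep(0L, 200)
  y[100:102] <- NA
  expect_false(window_scan(y, ds$map)[101])
  # chromosome shorter than one window: nothing eligible
  short <- toy_dataset(matrix(0L, 1, 30), spacing_bp = 5e3)
  expect_false(any(window_scan(short$dosage[1, ], short$map)))
})

test_that("windowed detector equals the exhaustive oracle on clean data", {
  for (s in 1:8) {
    fx <- suppressWarnings(roh_fixture(n_samples = 2, seed = s))
    det <- detect_roh(fx$dataset)
    ora <- detect_roh_oracle(fx$dataset)
    expect_equal(det, ora, ignore_attr = TRUE)
    # and the detected segments are exactly the planted ones
    expect_equal(nrow(det), nrow(fx$truth))
  }
})

test_that("oracle splits interior hets that the windowed detector bridges", {
  m <- 1000
  base <- toy_dataset(matrix(1L, 1, m), spacing_bp = 5e3)
  seg <- data.frame(sample_id = "s1", chrom = 1L,
                    start_bp = base$map$pos_bp[100],
                    end_bp = base$map$pos_bp[500])
  fx <- plant_roh(base, seg, background = "het", seed = 1)
  ds <- fx$dataset
  ds$dosage[1, 300] <- 1L   # one interior het
  det <- detect_roh(ds)
  ora <- detect_roh_oracle(ds)
  expect_equal(nrow(det), 1)   # bridged
  expect_equal(nrow(ora), 2)   # split
  expect_equal(det$start_bp, base$map$pos_bp[100])
  expect_equal(det$end_bp, base$map$pos_bp[500])
})

test_that("run-level minimums reject short or sparse runs", {
  # 60 homozygous SNPs spanning ~80 kb: enough SNPs, too short
  m <- 400
  map <- data.frame(marker_id = paste0("m", 1:m), chrom = 1L,
                    pos_bp = as.integer(seq(1337, by = 1337,
                                            length.out = m)),
                    allele1 = "A", allele2 = "B")
  x <- rep(1L, m)
  x[100:159] <- 0L   # 60 SNPs * 1337 bp ~ 79 kb
  ds <- genotype_dataset(matrix(x, 1), map, "s1")
  expect_equal(nrow(detect_roh(ds)), 0)
  expect_equal(nrow(detect_roh_oracle(ds)), 0)
  # alternating hets genome-wide: no ROH at all
  alt <- toy_dataset(matrix(1L, 2, 600), spacing_bp = 5e3)
  expect_equal(nrow(detect_roh(alt)), 0)
  # gap above 100 kb splits a run
  pos <- c(seq(5e3, by = 5e3, length.out = 300),
           seq(5e3 * 300 + 2e5, by = 5e3, length.out = 300))
  map2 <- data.frame(marker_id = paste0("g", 1:600), chrom = 1L,
                     pos_bp = as.integer(pos), allele1 = "A",
                     allele2 = "B")
  ds2 <- genotype_dataset(matrix(0L, 1, 600), map2, "s1")
  expect_equal(nrow(detect_roh(ds2)), 2)
})

test_that("froh is the ROH share of the genome", {
  rs <- data.frame(sample_id = "s1", chrom = 1L, start_bp = 1,
                   end_bp = 1e8, n_snps = 1000L, length_bp = 1e8)
  class(rs) <- c("roh_set", "data.frame")
  ft <- froh(rs, genome_length_bp = 2e9, sample_ids = c("s1", "s2"))
  expect_equal(ft$F_ROH, c(0.05, 0))   # zero-ROH sample reported as 0
  expect_error(froh(rs, genome_length_bp = 5e7, sample_ids = "s1"),
               "exceeds")
  # F_ROH monotone in planted total length
  base <- toy_dataset(matrix(1L, 1, 2000), spacing_bp = 5e3)
  lens <- c(100, 300, 600)
  fr <- sapply(lens, function(L) {
    seg <- data.frame(sample_id = "s1", chrom = 1L,
                      start_bp = base$map$pos_bp[100],
                      end_bp = base$map$pos_bp[100 + L])
    fx <- plant_roh(base, seg, background = "het", seed = 1)
    froh(detect_roh(fx$dataset), fx$dataset)$F_ROH
  })
  expect_true(all(diff(fr) > 0))
})

test_that("planted >=1 Mb segments are recalled under het errors", {
  # Hardy-Weinberg background, 0.5% heterozygote error inside segments
  set.seed(33)
  base <- toy_dataset(matrix(1L, 3, 3000), spacing_bp = 5e3)
  segs <- do.call(rbind, lapply(1:3, function(i) {
    s <- 300 + (i - 1) * 900
    data.frame(sample_id = paste0("s", i), chrom = 1L,
               start_bp = base$map$pos_bp[s],
               end_bp = base$map$pos_bp[s + 240])  # 1.2 Mb
  }))
  fx <- plant_roh(base, segs, het_error_rate = 0.005, seed = 12)
  det <- detect_roh(fx$dataset)
  hits <- 0
  for (r in seq_len(nrow(segs))) {
    d <- det[det$sample_id == segs$sample_id[r], , drop = FALSE]
    cov <- sum(pmax(0, pmin(d$end_bp, segs$end_bp[r]) -
                      pmax(d$start_bp, segs$start_bp[r])))
    if (cov >= 0.9 * (segs$end_bp[r] - segs$start_bp[r])) hits <- hits + 1
  }
  expect_equal(hits, nrow(segs))
})
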