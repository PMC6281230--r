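test_that("founder generator honors the frequency spectrum and seed", {
  s1 <- sim_founders(10, 100, chromosomes = 2,
                     freq_par = c(0.5, 0.5), seed = 2)
  expect_true(all(s1$p == 0.5))
  expect_lt(abs(mean(s1$dataset$dosage) - 1), 0.15)
  s2 <- sim_founders(10, 100, chromosomes = 2,
                     freq_par = c(0.5, 0.5), seed = 2)
  expect_identical(s1$dataset$dosage, s2$dataset$dosage)
  expect_identical(s1$haplotypes, s2$haplotypes)
  # U-shaped beta spectrum: KS non-rejection against Beta(0.5, 0.5)
  sb <- sim_founders(5, 4000, chromosomes = 2, freq_dist = "beta",
                     freq_par = c(0.5, 0.5), seed = 3)
  ks <- suppressWarnings(stats::ks.test(sb$p, stats::pbeta, 0.5, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene dropping is consistent between genotypes and truth", {
  ped <- full_sib_pedigree()
  fs <- sim_founders(2, 760, chromosomes = 38, seed = 4)
  gd <- gene_drop(fs, ped, seed = 10)
  # founders keep their haplotype genotypes
  expect_equal(unname(gd$dataset$dosage[1, ]),
               unname(fs$haplotypes[1, ] + fs$haplotypes[2, ]))
  # the inbred offspring's IBD segments are homozygous in the genotypes
  x5 <- gd$dataset$dosage[5, ]
  segs <- gd$ibd_segments[gd$ibd_segments$animal == "5", , drop = FALSE]
  if (nrow(segs)) {
    map <- gd$dataset$map
    for (r in seq_len(nrow(segs))) {
      sel <- map$chrom == segs$chrom[r] &
        map$pos_bp >= segs$start_bp[r] & map$pos_bp <= segs$end_bp[r]
      expect_true(all(x5[sel] != 1L))
    }
    # realized F equals the marker share flagged IBD
    expect_equal(gd$truth$realized_F[5],
                 sum(segs$n_snps) / nrow(map))
  }
  # mismatched founder count errors out
  expect_error(gene_drop(sim_founders(1, 76, chromosomes = 38, seed = 1),
                         ped), "founders")
})

test_that("Wright-Fisher drift fixes markers at tiny N", {
  wf <- sim_wright_fisher(N = 2, generations = 8, n_sample = 2,
                          m = 500, chromosomes = 2, seed = 5)
  # heterozygosity halves roughly every 2N generations at N = 2
  expect_lt(wf$truth$n_polymorphic, 250)
  expect_equal(wf$truth$n_polymorphic + wf$truth$n_fixed, 500)
  # running long enough fixes everything, which is an error condition
  expect_error(sim_wright_fisher(N = 2, generations = 60, n_sample = 2,
                                 m = 100, chromosomes = 2, seed = 5),
               "fixed")
})

test_that("admixture generator matches its stated model", {
  sim <- sim_admixture(K = 3, n = 50, m = 300, fst = 0.2,
                       dirichlet_alpha = 0.01, seed = 6)
  expect_equal(rowSums(sim$truth$Q), rep(1, 50))
  # alpha -> 0: individuals essentially unadmixed
  expect_gt(mean(apply(sim$truth$Q, 1, max)), 0.98)
  expect_true(all(sim$truth$P >= 0 & sim$truth$P <= 1))
  s2 <- sim_admixture(K = 3, n = 50, m = 300, fst = 0.2,
                      dirichlet_alpha = 0.01, seed = 6)
  expect_identical(sim$dataset$dosage, s2$dataset$dosage)
  # near-zero fst: populations indistinguishable
  flat <- sim_admixture(K = 2, n = 30, m = 200, fst = 1e-6, seed = 7)
  expect_lt(max(abs(flat$truth$P[1, ] - flat$truth$P[2, ])), 0.01)
})

test_that("plant_roh builds what it claims", {
  base <- toy_dataset(matrix(1L, 2, 800), spacing_bp = 5e3)
  seg <- data.frame(sample_id = "s1", chrom = 1L,
                    start_bp = base$map$pos_bp[101],
                    end_bp = base$map$pos_bp[500])
  fx <- plant_roh(base, seg, het_error_rate = 0, seed = 8)
  sel <- 101:500
  expect_true(all(fx$dataset$dosage[1, sel] != 1L))
  # expected het-error count ~ Binomial(400, 0.005) mean 2
  errs <- replicate(30, {
    f <- plant_roh(base, seg, het_error_rate = 0.005,
                   seed = sample.int(1e6, 1))
    sum(f$dataset$dosage[1, sel] == 1L)
  })
  expect_lt(abs(mean(errs) - 2), 1)
  # empty segment list: pure background
  fx0 <- plant_roh(base, seg[0, ], background = "het", seed = 1)
  expect_true(all(fx0$dataset$dosage == 1L))
  # overlapping segments merge with a warning
  two <- rbind(seg, within(seg, {
    start_bp <- base$map$pos_bp[400]
    end_bp <- base$map$pos_bp[600]
  }))
  expect_warning(fxm <- plant_roh(base, two, background = "het", seed = 2),
                 "merged")
  expect_equal(nrow(fxm$truth), 1)
  expect_equal(fxm$truth$end_bp, base$map$pos_bp[600])
})
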