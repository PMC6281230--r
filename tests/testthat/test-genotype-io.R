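test_that("text format recoding follows the dosage-of-allele2 convention", {
  td <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200"),
             file.path(td, "t.map"))
  writeLines("FAM1 A1 0 0 1 -9 A A A G",
             file.path(td, "t.ped"))
  ds <- read_plink_text(file.path(td, "t.ped"), file.path(td, "t.map"))
  # m1 monomorphic (A only) -> dosage 0; m2 het -> always 1
  expect_equal(unname(ds$dosage[1, ]), c(0L, 1L))
  writeLines("FAM1 A1 0 0 1 -9 0 0 G G", file.path(td, "t.ped"))
  ds <- read_plink_text(file.path(td, "t.ped"), file.path(td, "t.map"))
  expect_true(is.na(ds$dosage[1, 1]))  # "0 0" is missing
  writeLines("FAM1 A1 0 0 1 -9 A A A G A", file.path(td, "t.ped"))
  expect_error(read_plink_text(file.path(td, "t.ped"),
                               file.path(td, "t.map")), "line 1")
  writeLines(c("FAM1 A1 0 0 1 -9 A A A G",
               "FAM1 A2 0 0 1 -9 C C T G"), file.path(td, "t.ped"))
  expect_error(read_plink_text(file.path(td, "t.ped"),
                               file.path(td, "t.map")), "allele")
})

test_that("binary decode follows the 2-bit table, padding ignored", {
  td <- withr::local_tempdir()
  # 4 samples, 1 marker, byte 0b11011000 = 0xD8:
  # low-to-high pairs: 00, 10, 01, 11 -> hom-a1, het, missing, hom-a2
  writeLines("1\tm1\t0\t100\tA\tB", file.path(td, "t.bim"))
  writeLines(sprintf("F%d I%d 0 0 1 -9", 1:4, 1:4), file.path(td, "t.fam"))
  con <- file(file.path(td, "t.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xd8)), con)
  close(con)
  ds <- read_plink_binary(file.path(td, "t.bed"), file.path(td, "t.bim"),
                          file.path(td, "t.fam"))
  expect_equal(unname(ds$dosage[, 1]), c(0L, 1L, NA, 2L))

  # 5 samples -> 2 bytes per marker, last 6 bits are padding
  writeLines(sprintf("F%d I%d 0 0 1 -9", 1:5, 1:5), file.path(td, "t.fam"))
  con <- file(file.path(td, "t.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xd8, 0xff)), con)
  close(con)
  ds <- read_plink_binary(file.path(td, "t.bed"), file.path(td, "t.bim"),
                          file.path(td, "t.fam"))
  expect_equal(unname(ds$dosage[, 1]), c(0L, 1L, NA, 2L, 2L))

  # wrong magic
  con <- file(file.path(td, "t.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x00, 0x01, 0xd8, 0x00)), con)
  close(con)
  expect_error(read_plink_binary(file.path(td, "t.bed"),
                                 file.path(td, "t.bim"),
                                 file.path(td, "t.fam")), "magic")
  # truncated
  con <- file(file.path(td, "t.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xd8)), con)
  close(con)
  expect_error(read_plink_binary(file.path(td, "t.bed"),
                                 file.path(td, "t.bim"),
                                 file.path(td, "t.fam")), "truncat")
})

test_that("write-then-read round trips are the identity in both formats", {
  set.seed(7)
  for (fmt in c("text", "binary")) {
    sim <- sim_founders(20, 100, chromosomes = 2, seed = 17)
    ds <- sim$dataset
    ds$dosage[sample(length(ds$dosage), 30)] <- NA  # sprinkle missing
    td <- withr::local_tempdir()
    prefix <- file.path(td, "rt")
    write_genotypes(ds, prefix, fmt)
    back <- if (fmt == "text")
      read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
    else
      read_plink_binary(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                        paste0(prefix, ".fam"))
    expect_identical(unname(back$dosage), unname(ds$dosage))
    expect_equal(back$map$pos_bp, ds$map$pos_bp)
    expect_equal(back$sample_ids, ds$sample_ids)
  }
})

test_that("binary and text writers agree after re-reading", {
  sim <- sim_founders(7, 60, chromosomes = 3, seed = 23)
  td <- withr::local_tempdir()
  write_genotypes(sim$dataset, file.path(td, "a"), "text")
  write_genotypes(sim$dataset, file.path(td, "a"), "binary")
  t1 <- read_plink_text(file.path(td, "a.ped"), file.path(td, "a.map"))
  t2 <- read_plink_binary(file.path(td, "a.bed"), file.path(td, "a.bim"),
                          file.path(td, "a.fam"))
  expect_identical(unname(t1$dosage), unname(t2$dosage))
})

test_that("empty and single-genotype datasets survive writing", {
  empty <- genotype_dataset(matrix(integer(0), nrow = 2, ncol = 0),
                            data.frame(marker_id = character(0),
                                       chrom = integer(0),
                                       pos_bp = integer(0),
                                       allele1 = character(0),
                                       allele2 = character(0)),
                            c("a", "b"))
  td <- withr::local_tempdir()
  write_genotypes(empty, file.path(td, "e"), "binary")
  back <- read_plink_binary(file.path(td, "e.bed"), file.path(td, "e.bim"),
                            file.path(td, "e.fam"))
  expect_equal(nrow(back$map), 0)
  one <- toy_dataset(matrix(1L, 1, 1))
  write_genotypes(one, file.path(td, "o"), "text")
  line <- readLines(file.path(td, "o.ped"))
  g <- strsplit(line, " ")[[1]]
  expect_setequal(g[7:8], c("A", "B"))  # het written as an A/B pair
})

test_that("pedigree reading normalizes, reorders and rejects cycles", {
  td <- withr::local_tempdir()
  p <- file.path(td, "ped.txt")
  # child listed before parents -> reordered topologically
  writeLines(c("kid dad mom", "dad 0 0", "mom 0 0"), p)
  ped <- read_pedigree(p)
  expect_lt(match("dad", ped$animal), match("kid", ped$animal))
  expect_lt(match("mom", ped$animal), match("kid", ped$animal))
  expect_true(is.na(ped$sire[ped$animal == "dad"]))
  # founders only
  writeLines(c("a 0 0", "b 0 0"), p)
  expect_true(all(is.na(read_pedigree(p)$sire)))
  # self-ancestry
  writeLines("a a 0", p)
  expect_error(read_pedigree(p), "cycle")
  # longer cycle
  writeLines(c("a b 0", "b a 0"), p)
  expect_error(read_pedigree(p), "cycle")
  # duplicate animal
  writeLines(c("a 0 0", "a 0 0"), p)
  expect_error(read_pedigree(p), "duplicate")
})

test_that("unreferenced parents become implicit founders", {
  ped <- pedigree_table(c("x"), c("s1"), c("d1"))
  expect_setequal(ped$animal, c("x", "s1", "d1"))
  expect_true(all(is.na(ped$sire[ped$animal != "x"])))
})

test_that("recode_minor orients allele2 to the minor allele", {
  ds <- toy_dataset(rbind(c(2L, 0L), c(2L, 1L), c(1L, 0L)))
  rec <- recode_minor(ds)
  p <- allele_frequencies(rec)$p
  expect_true(all(p <= 0.5))
  # flipping twice is idempotent
  expect_identical(recode_minor(rec)$dosage, rec$dosage)
})
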