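test_that("dataset construction validates and enforces strand structure", {
  v <- snp_variants("chr1", 100L, ref = "A", alt = "G")
  cnt <- zero_tensor(1, 1)
  cnt[1, 1, nt_index("A"), 3] <- 3L
  cnt[1, 1, nt_index("G"), 3] <- 1L
  ds <- build_dataset(cnt, v, "s1", "unstranded")
  expect_s3_class(ds, "ase_dataset")
  expect_equal(sum(ds$counts[, , , "both"]), 4L)

  # stranded input: 'both' recomputed as plus + minus
  cnt2 <- zero_tensor(1, 1)
  cnt2[1, 1, , 1] <- c(2L, 0L, 0L, 0L)
  cnt2[1, 1, , 2] <- c(1L, 0L, 0L, 0L)
  ds2 <- build_dataset(cnt2, v, "s1", "fr-firststrand")
  expect_equal(as.integer(ds2$counts[1, 1, , "both"]), c(3L, 0L, 0L, 0L))

  bad <- cnt; bad[1, 1, 1, 3] <- -1L
  expect_error(build_dataset(bad, v, "s1", "unstranded"), "nonnegative")
  expect_error(build_dataset(cnt, v, "s1", "rf-stranded"), "strandedness")
  expect_error(build_dataset(zero_tensor(2, 1), v, "s1", "unstranded"),
               "samples x variants")
  # unstranded data must not carry plus/minus counts
  expect_error(build_dataset(cnt2, v, "s1", "unstranded"), "both")
})

test_that("region and sample subsetting keep exactly the requested slice", {
  v <- snp_variants("chr1", c(10L, 20L, 30L), ref = "A", alt = "G")
  cnt <- zero_tensor(3, 3)
  for (i in 1:3) for (j in 1:3) cnt[i, j, 1, 3] <- i * 10L + j
  ds <- build_dataset(cnt, v, c("s1", "s2", "s3"), "unstranded")

  sub <- subset_dataset(ds, region = "chr1:15-30")
  expect_equal(sub$variants$pos, c(20L, 30L))

  expect_equal(nrow(subset_dataset(ds, region = "chrX:1-100")$variants), 0L)

  one <- subset_dataset(ds, samples = "s2")
  expect_equal(dim(one$counts)[1], 1L)
  expect_equal(one$counts[1, , , ], ds$counts[2, , , ])

  expect_error(subset_dataset(ds, samples = "nope"), "unknown sample")

  # idempotence and identity
  r <- "chr1:10-30"
  expect_equal(subset_dataset(subset_dataset(ds, r), r)$counts,
               subset_dataset(ds, r)$counts)
  full <- subset_dataset(ds, region = "chr1:1-1000",
                         samples = c("s1", "s2", "s3"))
  expect_equal(full$counts, ds$counts)
})

test_that("allele fractions follow ref/(ref+alt) with an explicit depth gate", {
  k <- matrix(c(3, 0, 5), 1)
  a <- matrix(c(1, 0, 5), 1)
  ds <- ds_from_ref_alt(k, a)
  f <- allele_fractions(ds, min_depth = 1)
  expect_equal(as.numeric(f), c(0.75, NA, 0.5))

  # counts on the other two nucleotides are ignored
  ds$counts[1, 1, nt_index("C"), 3] <- 50L
  expect_equal(allele_fractions(ds)[1, 1], 0.75)

  # fraction complement: swapping ref/alt mirrors the fraction
  swapped <- ds
  swapped$variants$ref <- ds$variants$alt
  swapped$variants$alt <- ds$variants$ref
  f1 <- allele_fractions(ds); f2 <- allele_fractions(swapped)
  ok <- !is.na(f1)
  expect_equal(f1[ok] + f2[ok], rep(1, sum(ok)))

  # unresolved alleles are a state error pointing at the fix
  v <- snp_variants("chr1", 1L)
  ds0 <- build_dataset(zero_tensor(1, 1), v, "s1", "unstranded")
  expect_error(allele_fractions(ds0), "resolve_alleles")
})

test_that("top_alleles ranks by count with alphabetical ties and metadata priority", {
  v <- snp_variants("chr1", c(10L, 20L, 30L, 40L))
  v$ref[3] <- "G"; v$alt[3] <- "A"
  cnt <- zero_tensor(1, 4)
  cnt[1, 1, , 3] <- c(90L, 3L, 85L, 0L)   # A, G top two
  cnt[1, 2, , 3] <- c(10L, 10L, 0L, 0L)   # A, C tie-break
  cnt[1, 3, , 3] <- c(99L, 99L, 0L, 0L)   # metadata wins regardless
  ds <- build_dataset(cnt, v, "s1", "unstranded")
  ta <- top_alleles(ds)
  expect_equal(ta$ref[1:3], c("A", "A", "G"))
  expect_equal(ta$alt[1:3], c("G", "C", "A"))
  expect_equal(ta$source[3], "given")
  # zero-count variant: alphabetical pair, flagged
  expect_equal(c(ta$ref[4], ta$alt[4]), c("A", "C"))
  expect_true(ta$low_confidence[4])
})

test_that("genotype inference applies depth gate, het band and provided overrides", {
  k <- matrix(c(12, 20, 2), 1)
  a <- matrix(c(8, 0, 1), 1)
  ds <- ds_from_ref_alt(k, a)
  gt <- infer_genotypes(ds, min_depth = 10, het_low = 0.10)
  expect_equal(as.character(gt), c("0/1", "0/0", NA))

  # hom-alt called when alt dominates
  ds2 <- ds_from_ref_alt(matrix(0, 1), matrix(30, 1))
  expect_equal(as.character(infer_genotypes(ds2)), "1/1")

  # provided genotypes always win
  prov <- matrix(c("1/1", NA, "0/1"), 1)
  ds$genotypes <- prov; dimnames(ds$genotypes) <- dimnames(gt)
  gt2 <- infer_genotypes(ds)
  expect_equal(as.character(gt2), c("1/1", "0/0", "0/1"))
})

test_that("a balanced het cell at depth 30 is essentially always called het", {
  set.seed(42)
  n_cells <- 1000
  k <- matrix(rbinom(n_cells, 30, 0.5), 1)
  ds <- ds_from_ref_alt(k, 30 - k)
  gt <- infer_genotypes(ds, min_depth = 10, het_low = 0.10)
  expect_gte(sum(gt == "0/1"), 999)
})

test_that("MAF counts alleles over diploid calls and filters strictly", {
  # 8 samples: 6 hom-ref, 2 het -> f = 14/16, MAF = 0.125
  gt <- matrix(c(rep("0/0", 6), rep("0/1", 2)), ncol = 1)
  ds <- ds_from_ref_alt(matrix(20, 8, 1), matrix(20, 8, 1), genotypes = gt)
  m <- maf(ds, genotypes = ds$genotypes)
  expect_equal(unname(m), 0.125)
  expect_equal(nrow(maf_filter(ds, 0.1, genotypes = ds$genotypes)$variants), 1L)

  # all hom-ref -> MAF 0, removed at 0.1
  gt0 <- matrix(rep("0/0", 8), ncol = 1)
  ds0 <- ds_from_ref_alt(matrix(20, 8, 1), matrix(0, 8, 1), genotypes = gt0)
  expect_equal(unname(maf(ds0, ds0$genotypes)), 0)
  expect_equal(nrow(maf_filter(ds0, 0.1, ds0$genotypes)$variants), 0L)

  # 4 het of 4 called -> maximum 0.5
  gt4 <- matrix(rep("0/1", 4), ncol = 1)
  ds4 <- ds_from_ref_alt(matrix(15, 4, 1), matrix(15, 4, 1), genotypes = gt4)
  expect_equal(unname(maf(ds4, ds4$genotypes)), 0.5)

  # zero called samples -> missing
  gtn <- matrix(NA_character_, 4, 1)
  expect_true(is.na(maf(ds4, gtn)))

  # bounds property over random genotype matrices
  set.seed(7)
  for (rep in 1:20) {
    g <- matrix(sample(c("0/0", "0/1", "1/1", NA), 12, replace = TRUE), 6, 2)
    dsr <- ds_from_ref_alt(matrix(20, 6, 2), matrix(20, 6, 2))
    m <- maf(dsr, g)
    expect_true(all(is.na(m) | (m >= 0 & m <= 0.5)))
  }
})

test_that("wide-TSV serialization round-trips counts, genotypes and phenotypes", {
  set.seed(11)
  v <- snp_variants(c("chr1", "chr1", "chr2"), c(50L, 150L, 70L),
                    ref = c("A", "C", NA), alt = c("G", "T", NA))
  cnt <- zero_tensor(2, 3)
  cnt[, , , 1] <- array(rpois(24, 5), c(2, 3, 4))
  cnt[, , , 2] <- array(rpois(24, 5), c(2, 3, 4))
  gt <- matrix(sample(c("0/0", "0/1", "1/1", NA), 6, TRUE), 2, 3)
  ph <- data.frame(tissue = c("liver", "aorta"), row.names = c("s1", "s2"))
  ds <- build_dataset(cnt, v, c("s1", "s2"), "fr-firststrand",
                      phenotypes = ph, genotypes = gt)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, path)
  back <- read_dataset_tsv(path)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$variants, ds$variants, ignore_attr = TRUE)
  expect_equal(back$strandedness, ds$strandedness)
  expect_equal(back$genotypes, ds$genotypes)
  expect_equal(back$phenotypes$tissue, ph$tissue)
})
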