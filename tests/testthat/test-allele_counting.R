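# SNP at chr1:50 in most fixtures; reads are 10 bp, so a read at pos 45
# covers the SNP at query offset 6.
snp <- function(ref = "A", alt = "G") snp_variants("chr1", 50L, ref = ref,
                                                   alt = alt)

test_that("admitted reads are tallied per base; filters drop the rest", {
  reads <- rbind(
    read_row("r1", 45, "CCCCCACCCC"),            # A at SNP
    read_row("r2", 46, "CCCCACCCCC"),            # A
    read_row("r3", 50, "ACCCCCCCCC"),            # A (SNP at first base)
    read_row("r4", 41, "CCCCCCCCCG"),            # G (SNP at last base)
    read_row("r5", 48, "CCGCCCCCCC"))            # G
  bam <- sam_fixture(reads)
  filt <- count_filter(require_proper_pair = FALSE)
  ds <- count_alleles(c(s1 = bam), snp(), filter = filt)
  expect_equal(ds$counts["s1", 1, "A", "both"], 3L)
  expect_equal(ds$counts["s1", 1, "G", "both"], 2L)

  # one A-read drops below the MAPQ threshold
  reads$mapq[1] <- 5L
  ds2 <- count_alleles(c(s1 = sam_fixture(reads)), snp(), filter = filt)
  expect_equal(ds2$counts["s1", 1, "A", "both"], 2L)
  expect_equal(counting_report(ds2)$mapq, 1L)

  # MAPQ exactly at the threshold is admitted (inclusive)
  reads$mapq[1] <- 20L
  ds3 <- count_alleles(c(s1 = sam_fixture(reads)), snp(), filter = filt)
  expect_equal(ds3$counts["s1", 1, "A", "both"], 3L)
})

test_that("reads without an aligned base at the SNP contribute nothing", {
  reads <- rbind(
    read_row("d1", 45, "CCCCCCCCCC", cigar = "5M2D5M"),  # deletion spans 50
    read_row("n1", 45, "CCCCCCCCCC", cigar = "5M10N5M"), # skip spans 50
    read_row("s1", 48, "CCCCCCCCCC", cigar = "5S5M"),    # SNP soft-clipped?
    read_row("ok", 45, "CCCCCTCCCC"))                    # T at SNP
  # s1: pos 48 with 5S5M -> aligned span 48..52 covers 50 at query 5+3=8? no:
  # query offset = 5 (clip) + (50-48+1) = 8 -> base 'C'; keep it aligned,
  # replace with an N to exercise the non-ACGT rule
  reads$seq[3] <- "CCCCCCCNCC"
  bam <- sam_fixture(reads)
  ds <- count_alleles(c(s1 = bam), snp(ref = "T", alt = "C"),
                      filter = count_filter(require_proper_pair = FALSE))
  expect_equal(sum(ds$counts["s1", 1, , "both"]), 1L)
  expect_equal(ds$counts["s1", 1, "T", "both"], 1L)
  expect_equal(counting_report(ds)$no_base, 3L)
})

test_that("duplicate, secondary and base-quality rules reject with reasons", {
  reads <- rbind(
    read_row("r1", 45, "CCCCCACCCC", flag = 1024L),       # duplicate
    read_row("r2", 45, "CCCCCACCCC", flag = 256L),        # secondary
    read_row("r3", 45, "CCCCCACCCC", qual_char = "#"),    # baseQ 2
    read_row("r4", 45, "CCCCCACCCC"))
  bam <- sam_fixture(reads)
  ds <- count_alleles(c(s1 = bam), snp(),
                      filter = count_filter(require_proper_pair = FALSE))
  rep <- counting_report(ds)
  expect_equal(ds$counts["s1", 1, "A", "both"], 1L)
  expect_equal(rep$duplicate, 1L)
  expect_equal(rep$secondary, 1L)
  expect_equal(rep$baseq, 1L)

  # admit_read exposes the same decisions one read at a time
  expect_true(admit_read(list(flag = 99L, mapq = 30L, baseq = 35L))$admitted)
  r <- admit_read(list(flag = 1024L, mapq = 60L, baseq = 40L))
  expect_false(r$admitted)
  expect_equal(r$reason, "duplicate")
  expect_equal(admit_read(list(flag = 1L, mapq = 60L, baseq = 40L))$reason,
               "not_proper")
})

test_that("a fragment overlapping the SNP in both mates is counted once", {
  pair <- function(qn, base) rbind(
    read_row(qn, 45, sub("X", base, "CCCCCXCCCC"), flag = 99L),
    read_row(qn, 48, sub("X", base, "CCXCCCCCCC"), flag = 147L))
  bam <- sam_fixture(rbind(pair("f1", "A"), pair("f2", "G")))
  ds <- count_alleles(c(s1 = bam), snp(), filter = count_filter())
  expect_equal(ds$counts["s1", 1, "A", "both"], 1L)
  expect_equal(ds$counts["s1", 1, "G", "both"], 1L)

  # when the first-encountered mate has no usable base the partner counts
  broken <- rbind(read_row("f3", 45, "CCCCCNCCCC", flag = 99L),
                  read_row("f3", 48, "CCACCCCCCC", flag = 147L))
  ds2 <- count_alleles(c(s1 = sam_fixture(broken)), snp())
  expect_equal(ds2$counts["s1", 1, "A", "both"], 1L)
})

test_that("protocol strand follows read1/read2 orientation conventions", {
  # fr-firststrand: read2 carries the transcript orientation
  expect_equal(fragment_strand(0x80L, "fr-firststrand"), "plus")
  expect_equal(fragment_strand(0x80L + 0x10L, "fr-firststrand"), "minus")
  expect_equal(fragment_strand(0x40L, "fr-firststrand"), "minus")
  expect_equal(fragment_strand(0x40L + 0x10L, "fr-firststrand"), "plus")
  # fr-secondstrand is the inverse
  expect_equal(fragment_strand(0x80L, "fr-secondstrand"), "minus")
  expect_equal(fragment_strand(0x40L, "fr-secondstrand"), "plus")
  # single-end reads are treated as read1
  expect_equal(fragment_strand(0L, "fr-firststrand"), "minus")
  expect_equal(fragment_strand(0x10L, "fr-firststrand"), "plus")
  # unstranded: everything lands on 'both'
  expect_equal(fragment_strand(c(0L, 0x40L, 0x90L), "unstranded"),
               rep("both", 3))
  expect_error(fragment_strand(0x40L + 0x80L, "fr-firststrand"), "malformed")
})

test_that("stranded counting matches a hand-built fixture with known truth", {
  # two fragments on the plus transcript (read2 forward), one on minus
  reads <- rbind(
    read_row("p1", 45, "CCCCCACCCC", flag = 163L),  # read2 fwd -> plus
    read_row("p1", 48, "CCACCCCCCC", flag = 83L),
    read_row("p2", 44, "CCCCCCACCC", flag = 163L),
    read_row("p2", 49, "CACCCCCCCC", flag = 83L),
    read_row("m1", 45, "CCCCCGCCCC", flag = 99L),   # read1 fwd -> minus
    read_row("m1", 48, "CCGCCCCCCC", flag = 147L))
  bam <- sam_fixture(reads)
  ds <- count_alleles(c(s1 = bam), snp(), strandedness = "fr-firststrand")
  expect_equal(ds$counts["s1", 1, "A", "plus"], 2L)
  expect_equal(ds$counts["s1", 1, "G", "minus"], 1L)
  expect_equal(ds$counts["s1", 1, "A", "both"], 2L)
  # same fixture under fr-secondstrand swaps the strands
  ds2 <- count_alleles(c(s1 = bam), snp(), strandedness = "fr-secondstrand")
  expect_equal(ds2$counts["s1", 1, "A", "minus"], 2L)
  expect_equal(ds2$counts["s1", 1, "G", "plus"], 1L)
})

test_that("counting equals the brute-force oracle on simulated data", {
  for (mode in c("unstranded", "fr-firststrand")) {
    cfg <- sim_config(n_snps = 6, n_samples = 2, depth = 30,
                      strandedness = mode, error_rate = 0.01,
                      seed = 17 + nchar(mode))
    sim <- simulate_ase(cfg, withr::local_tempdir())
    v <- read_variants(sim$vcf)$variants
    filt <- count_filter()
    ds <- count_alleles(sim$bams, v, filter = filt, strandedness = mode)
    for (s in names(sim$bams)) {
      want <- oracle_count_bam(sim$bams[[s]], v, filt, mode)
      expect_equal(ds$counts[s, , , ], want, ignore_attr = TRUE)
    }
  }
})

test_that("read order does not change counts", {
  cfg <- sim_config(n_snps = 4, n_samples = 1, depth = 25, seed = 5)
  sim <- simulate_ase(cfg, withr::local_tempdir())
  v <- read_variants(sim$vcf)$variants
  ds1 <- count_alleles(sim$bams, v, filter = permissive_filter())

  # shuffle the SAM body and re-sort
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "shuf.sam")
  Rsamtools::asSam(sim$bams[[1]], sub("\\.sam$", "", sam), overwrite = TRUE)
  lines <- readLines(sam)
  hdr <- grepl("^@", lines)
  set.seed(99)
  writeLines(c(lines[hdr], sample(lines[!hdr])), sam)
  bam2 <- Rsamtools::asBam(sam, file.path(dir, "shuf"), overwrite = TRUE,
                           indexDestination = TRUE)
  ds2 <- count_alleles(setNames(bam2, names(sim$bams)), v,
                       filter = permissive_filter())
  expect_equal(ds2$counts, ds1$counts, ignore_attr = TRUE)
})

test_that("missing index and absent chromosomes are reported as specified", {
  reads <- read_row("r1", 45, "CCCCCACCCC")
  bam <- sam_fixture(reads)
  file.remove(paste0(bam, ".bai"))
  expect_error(count_alleles(c(s1 = bam), snp()), "index")
  Rsamtools::indexBam(bam)

  v2 <- rbind(snp(), snp_variants("chrZ", 10L, ref = "A", alt = "C"))
  expect_warning(ds <- count_alleles(c(s1 = bam), v2,
                                     filter = count_filter(require_proper_pair = FALSE)),
                 "absent")
  expect_equal(sum(ds$counts[1, 2, , ]), 0L)
})
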