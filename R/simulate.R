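#' Configuration for the read simulator
#'
#' Describes a toy experiment: a uniform-random reference genome, `n_snps`
#' biallelic SNVs placed away from chromosome ends and spaced more than one
#' fragment length apart (so no fragment overlaps two SNPs), and per-sample
#' diploid genotypes with a true reference-allele fraction per heterozygous
#' cell. For every sample x SNP cell, exactly `depth` fragments are drawn;
#' their alleles come from `Binomial(depth, fraction)` for het cells (all
#' ref / all alt for homozygotes), and alt-allele fragments are then thinned
#' with probability `ref_bias` to emulate reference-mapping loss. Each
#' fragment becomes one FR read pair fully covering the fragment (mates
#' overlap in the middle), MAPQ 60, base quality 40, perfect-match CIGAR,
#' with first/second-in-pair flags consistent with the declared strandedness
#' protocol and the SNP's transcript strand.
#'
#' @param n_chroms number of chromosomes (default 1).
#' @param chrom_length length of each chromosome in bp (default 10000).
#' @param n_snps total number of SNVs (default 10).
#' @param n_samples number of samples (default 2).
#' @param genotypes optional `n_samples x n_snps` matrix of `0/0`, `0/1`,
#'   `1/1`; default all heterozygous.
#' @param fractions true reference-allele fraction for het cells: scalar or
#'   `n_samples x n_snps` matrix (default 0.5).
#' @param depth fragments drawn per sample x SNP cell (default 50).
#' @param read_length read length in bp (default 75).
#' @param fragment_length fragment length in bp; must satisfy
#'   `read_length <= fragment_length <= 2 * read_length` so the mate union
#'   covers the fragment (default 120).
#' @param strandedness library protocol (default `"unstranded"`).
#' @param ref_bias probability that an alt-allele fragment is lost
#'   (default 0).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 1L, chrom_length = 10000L, n_snps = 10L,
                       n_samples = 2L, genotypes = NULL, fractions = 0.5,
                       depth = 50L, read_length = 75L, fragment_length = 120L,
                       strandedness = "unstranded", ref_bias = 0,
                       error_rate = 0, seed = 1L) {
  strandedness <- match.arg(strandedness, .STRAND_MODES)
  stopifnot(depth >= 1L, n_snps >= 1L, n_samples >= 1L,
            ref_bias >= 0, ref_bias < 1, error_rate >= 0, error_rate < 1)
  if (fragment_length < read_length || fragment_length > 2L * read_length)
    stop("need read_length <= fragment_length <= 2*read_length so mates ",
         "cover the whole fragment")
  if (fragment_length > chrom_length)
    stop("fragment_length exceeds chrom_length")
  if (is.null(genotypes)) {
    genotypes <- matrix("0/1", n_samples, n_snps)
  } else {
    genotypes <- as.matrix(genotypes)
    stopifnot(identical(dim(genotypes), c(as.integer(n_samples),
                                          as.integer(n_snps))))
    if (any(!genotypes %in% c("0/0", "0/1", "1/1")))
      stop("genotypes must be 0/0, 0/1 or 1/1")
  }
  if (length(fractions) == 1L)
    fractions <- matrix(fractions, n_samples, n_snps)
  fractions <- as.matrix(fractions)
  stopifnot(identical(dim(fractions), dim(genotypes)),
            all(fractions >= 0), all(fractions <= 1))
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_snps = as.integer(n_snps), n_samples = as.integer(n_samples),
                 genotypes = genotypes, fractions = fractions,
                 depth = as.integer(depth), read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 strandedness = strandedness, ref_bias = ref_bias,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# distinct SNP slots: > fragment_length apart, >= read_length from ends
.place_snps <- function(config, n_on_chrom) {
  gap <- config$fragment_length + config$read_length
  lo <- config$read_length + config$fragment_length
  hi <- config$chrom_length - config$read_length - config$fragment_length
  slots <- seq.int(lo, hi, by = gap)
  if (length(slots) < n_on_chrom)
    stop("chromosome too short for ", n_on_chrom, " SNP(s): need about ",
         n_on_chrom * gap + 2L * lo, " bp, have ", config$chrom_length)
  sort(sample(slots, n_on_chrom))
}

#' Simulate an allele-specific expression experiment
#'
#' Writes into `out_dir`: `ref.fa` (toy reference), `variants.vcf`
#' (VCF 4.2, SNVs with per-sample GT), one coordinate-sorted indexed BAM per
#' sample (`<sample>.bam` + `.bai`), and `truth.tsv` with the realized
#' per-cell fragment counts by allele and transcript strand. Identical
#' config + seed reproduce identical FASTA/VCF/truth files and the same BAM
#' record set.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `fasta`, `vcf`, `bams` (named
#'   paths), `truth` (path) and `truth_table` (`data.frame`).
#' @export
simulate_ase <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  rl <- config$read_length; fl <- config$fragment_length

  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- lapply(chroms, function(ch)
    paste(sample(.NT, config$chrom_length, replace = TRUE), collapse = ""))
  names(genome) <- chroms

  # round-robin SNP placement across chromosomes
  snp_chrom <- chroms[((seq_len(config$n_snps) - 1L) %% config$n_chroms) + 1L]
  snp_pos <- integer(config$n_snps)
  for (ch in chroms) {
    idx <- which(snp_chrom == ch)
    if (length(idx)) snp_pos[idx] <- .place_snps(config, length(idx))
  }
  ref_allele <- vapply(seq_len(config$n_snps), function(j)
    substring(genome[[snp_chrom[j]]], snp_pos[j], snp_pos[j]), character(1))
  alt_allele <- vapply(ref_allele, function(r) sample(setdiff(.NT, r), 1L),
                       character(1), USE.NAMES = FALSE)
  snp_id <- sprintf("snp%03d", seq_len(config$n_snps))
  tx_strand <- sample(c("+", "-"), config$n_snps, replace = TRUE)
  samples <- sprintf("sample%02d", seq_len(config$n_samples))

  fasta <- file.path(out_dir, "ref.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome)), fasta, width = 60L)

  vcf <- file.path(out_dir, "variants.vcf")
  .write_sim_vcf(vcf, chroms, config$chrom_length, snp_chrom, snp_pos,
                 snp_id, ref_allele, alt_allele, config$genotypes, samples)

  truth <- NULL
  bam_paths <- character(0)
  for (si in seq_len(config$n_samples)) {
    recs <- list()
    for (j in seq_len(config$n_snps)) {
      gt <- config$genotypes[si, j]
      n_ref <- switch(gt,
        "0/0" = config$depth,
        "1/1" = 0L,
        "0/1" = rbinom(1L, config$depth, config$fractions[si, j]))
      n_alt <- config$depth - n_ref
      if (config$ref_bias > 0 && n_alt > 0L)
        n_alt <- rbinom(1L, n_alt, 1 - config$ref_bias)
      truth <- rbind(truth, data.frame(
        sample = samples[si], chrom = snp_chrom[j], pos = snp_pos[j],
        id = snp_id[j], ref = ref_allele[j], alt = alt_allele[j], gt = gt,
        true_fraction = if (gt == "0/1") config$fractions[si, j]
                        else as.numeric(gt == "0/0"),
        tx_strand = tx_strand[j], ref_count = n_ref, alt_count = n_alt,
        stringsAsFactors = FALSE))
      if (n_ref + n_alt == 0L) next
      recs[[length(recs) + 1L]] <- .sim_fragments(
        config, genome[[snp_chrom[j]]], snp_chrom[j], snp_pos[j],
        alt_allele[j], n_ref, n_alt, tx_strand[j],
        qprefix = paste0("f_", samples[si], "_", snp_id[j]))
    }
    sam <- file.path(out_dir, paste0(samples[si], ".sam"))
    .write_sam(sam, chroms, config$chrom_length,
               if (length(recs)) do.call(rbind, recs) else NULL)
    bam <- Rsamtools::asBam(sam, file.path(out_dir, samples[si]),
                            overwrite = TRUE, indexDestination = TRUE)
    bam_paths[samples[si]] <- bam
    unlink(sam)
  }

  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(dir = out_dir, fasta = fasta, vcf = vcf, bams = bam_paths,
                 truth = truth_path, truth_table = truth))
}

# emit SAM fields for n_ref + n_alt fragments over one SNP
.sim_fragments <- function(config, chrom_seq, chrom, pos, alt, n_ref, n_alt,
                           tx_strand, qprefix) {
  rl <- config$read_length; fl <- config$fragment_length
  n <- n_ref + n_alt
  is_alt <- rep(c(FALSE, TRUE), c(n_ref, n_alt))
  fstart <- sample(fl, n, replace = TRUE) + pos - fl  # in [pos-fl+1, pos]
  fend <- fstart + fl - 1L
  # forward mate at fstart, reverse mate ending at fend
  fwd_seq <- substring(chrom_seq, fstart, fstart + rl - 1L)
  rev_seq <- substring(chrom_seq, fend - rl + 1L, fend)
  rel_f <- pos - fstart + 1L
  rel_r <- pos - (fend - rl + 1L) + 1L
  covers_f <- rel_f >= 1L & rel_f <= rl
  covers_r <- rel_r >= 1L & rel_r <= rl
  w <- which(is_alt & covers_f)
  substr(fwd_seq[w], rel_f[w], rel_f[w]) <- alt
  w <- which(is_alt & covers_r)
  substr(rev_seq[w], rel_r[w], rel_r[w]) <- alt
  if (config$error_rate > 0) {
    fwd_seq <- .inject_errors(fwd_seq, config$error_rate)
    rev_seq <- .inject_errors(rev_seq, config$error_rate)
  }

  # which physical mate is first-in-pair: for fr-firststrand read2 carries
  # the transcript orientation; for fr-secondstrand read1 does; unstranded
  # libraries get a random assignment.
  fwd_is_read2 <- switch(config$strandedness,
    "fr-firststrand" = rep(tx_strand == "+", n),
    "fr-secondstrand" = rep(tx_strand == "-", n),
    "unstranded" = sample(c(TRUE, FALSE), n, replace = TRUE))
  base_flag <- .FLAG_PAIRED + .FLAG_PROPER
  fwd_flag <- base_flag + .FLAG_MATE_REVERSE +
    ifelse(fwd_is_read2, .FLAG_READ2, .FLAG_READ1)
  rev_flag <- base_flag + .FLAG_REVERSE +
    ifelse(fwd_is_read2, .FLAG_READ1, .FLAG_READ2)

  qname <- paste0(qprefix, "_", seq_len(n))
  qual <- strrep(rawToChar(as.raw(40L + 33L)), rl)
  cigar <- paste0(rl, "M")
  data.frame(
    qname = rep(qname, 2L),
    flag = c(fwd_flag, rev_flag),
    rname = chrom,
    pos = c(fstart, fend - rl + 1L),
    mapq = 60L,
    cigar = cigar,
    rnext = "=",
    pnext = c(fend - rl + 1L, fstart),
    tlen = c(rep(fl, n), rep(-fl, n)),
    seq = c(fwd_seq, rev_seq),
    qual = qual,
    stringsAsFactors = FALSE
  )
}

.inject_errors <- function(seqs, rate) {
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    n_err <- rbinom(1L, L, rate)
    if (n_err == 0L) next
    at <- sample(L, n_err)
    for (p in at) {
      cur <- substring(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(.NT, cur), 1L)
    }
  }
  seqs
}

.write_sam <- function(path, chroms, chrom_length, recs) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", chroms, "\tLN:", chrom_length))
  body <- character(0)
  if (!is.null(recs) && nrow(recs))
    body <- paste(recs$qname, recs$flag, recs$rname, recs$pos, recs$mapq,
                  recs$cigar, recs$rnext, recs$pnext, recs$tlen, recs$seq,
                  recs$qual, sep = "\t")
  writeLines(c(hdr, body), path)
}

.write_sim_vcf <- function(path, chroms, chrom_length, snp_chrom, snp_pos,
                           snp_id, ref, alt, genotypes, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chroms, ",length=", chrom_length, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  ord <- order(match(snp_chrom, chroms), snp_pos)
  rows <- vapply(ord, function(j)
    paste(c(snp_chrom[j], snp_pos[j], snp_id[j], ref[j], alt[j], ".",
            "PASS", ".", "GT", genotypes[, j]), collapse = "\t"),
    character(1))
  writeLines(c(hdr, rows), path)
}

#' Check that recounting the simulated BAMs reproduces the truth table
#'
#' Runs [count_alleles()] with a [permissive_filter()] on the simulator's
#' output and compares the realized ref/alt fragment counts per sample x
#' SNP (and their transcript-strand placement, for stranded protocols) with
#' `truth.tsv`. Exact equality is expected at `error_rate = 0`.
#'
#' @param out_dir directory written by [simulate_ase()].
#' @param strandedness the protocol the simulation used; default is read
#'   from the recount of flags (must match the config).
#' @return `TRUE`/`FALSE` with attribute `diffs`, a `data.frame` of
#'   mismatching cells.
#' @export
recount_equals_truth <- function(out_dir, strandedness = NULL) {
  truth <- read.delim(file.path(out_dir, "truth.tsv"),
                      stringsAsFactors = FALSE)
  rv <- read_variants(file.path(out_dir, "variants.vcf"))
  samples <- sort(unique(truth$sample))
  bams <- setNames(file.path(out_dir, paste0(samples, ".bam")), samples)
  if (is.null(strandedness)) {
    # infer: a simulated unstranded library is declared as such by the
    # caller; default to unstranded when not told otherwise
    strandedness <- "unstranded"
  }
  ds <- count_alleles(bams, rv$variants, filter = permissive_filter(),
                      strandedness = strandedness)
  diffs <- list()
  for (r in seq_len(nrow(truth))) {
    s <- truth$sample[r]; id <- truth$id[r]
    for (al in c("ref", "alt")) {
      nt <- truth[[al]][r]
      want <- truth[[paste0(al, "_count")]][r]
      if (strandedness == "unstranded") {
        got <- ds$counts[s, id, nt, "both"]
      } else {
        st <- if (truth$tx_strand[r] == "+") "plus" else "minus"
        got <- ds$counts[s, id, nt, st]
      }
      if (got != want)
        diffs[[length(diffs) + 1L]] <- data.frame(
          sample = s, id = id, allele = al, expected = want, observed = got,
          stringsAsFactors = FALSE)
    }
  }
  diffs <- if (length(diffs)) do.call(rbind, diffs)
           else data.frame(sample = character(), id = character(),
                           allele = character(), expected = integer(),
                           observed = integer())
  structure(nrow(diffs) == 0L, diffs = diffs)
}
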