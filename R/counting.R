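# SAM flag bits
.FLAG_PAIRED <- 0x1L
.FLAG_PROPER <- 0x2L
.FLAG_UNMAPPED <- 0x4L
.FLAG_REVERSE <- 0x10L
.FLAG_MATE_REVERSE <- 0x20L
.FLAG_READ1 <- 0x40L
.FLAG_READ2 <- 0x80L
.FLAG_SECONDARY <- 0x100L
.FLAG_DUP <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

.REJECT_TOKENS <- c("unmapped", "secondary", "duplicate", "not_proper",
                    "mapq", "baseq", "no_base")

#' Read-admission rules for allele counting
#'
#' @param min_mapq minimum mapping quality (inclusive; default 20).
#' @param min_baseq minimum base quality at the SNP base (inclusive;
#'   default 10).
#' @param require_proper_pair drop paired reads without the proper-pair flag
#'   (default `TRUE`; ignored for single-end reads).
#' @param drop_duplicates drop PCR/optical duplicates (default `TRUE`).
#' @param drop_secondary_supplementary drop secondary and supplementary
#'   alignments (default `TRUE`).
#' @return a `count_filter` list.
#' @export
count_filter <- function(min_mapq = 20L, min_baseq = 10L,
                         require_proper_pair = TRUE, drop_duplicates = TRUE,
                         drop_secondary_supplementary = TRUE) {
  stopifnot(min_mapq >= 0L, min_baseq >= 0L,
            is.logical(require_proper_pair), is.logical(drop_duplicates),
            is.logical(drop_secondary_supplementary))
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 require_proper_pair = isTRUE(require_proper_pair),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_secondary_supplementary =
                   isTRUE(drop_secondary_supplementary)),
            class = "count_filter")
}

#' A filter that admits every aligned read with a called base
#' @return a `count_filter` with all thresholds at zero and flag rules off.
#' @export
permissive_filter <- function() {
  count_filter(min_mapq = 0L, min_baseq = 0L, require_proper_pair = FALSE,
               drop_duplicates = FALSE, drop_secondary_supplementary = FALSE)
}

# vectorized admission: returns a token per read, "ok" when admitted.
# checks are ordered; the first failing rule names the rejection.
.admit_tokens <- function(flag, mapq, baseq, filter) {
  tok <- rep("ok", length(flag))
  fails <- function(bit) bitwAnd(flag, bit) > 0L
  paired <- fails(.FLAG_PAIRED)
  tok[tok == "ok" & fails(.FLAG_UNMAPPED)] <- "unmapped"
  if (filter$drop_secondary_supplementary)
    tok[tok == "ok" & (fails(.FLAG_SECONDARY) | fails(.FLAG_SUPPLEMENTARY))] <-
      "secondary"
  if (filter$drop_duplicates)
    tok[tok == "ok" & fails(.FLAG_DUP)] <- "duplicate"
  if (filter$require_proper_pair)
    tok[tok == "ok" & paired & !fails(.FLAG_PROPER)] <- "not_proper"
  mapq_bad <- is.na(mapq) | mapq < filter$min_mapq
  tok[tok == "ok" & mapq_bad] <- "mapq"
  baseq_bad <- !is.na(baseq) & baseq < filter$min_baseq
  tok[tok == "ok" & baseq_bad] <- "baseq"
  tok
}

#' Decide whether one alignment record is counted
#'
#' @param read a list with elements `flag` (integer SAM flag), `mapq`, and
#'   `baseq` (base quality at the SNP base; `NA` when the read has no
#'   aligned base there).
#' @param filter a [count_filter()].
#' @return list with `admitted` (logical) and `reason` (`"ok"` or one of
#'   `unmapped`, `secondary`, `duplicate`, `not_proper`, `mapq`, `baseq`).
#' @examples
#' admit_read(list(flag = 99L, mapq = 30L, baseq = 35L), count_filter())
#' @export
admit_read <- function(read, filter = count_filter()) {
  tok <- .admit_tokens(as.integer(read$flag), read$mapq, read$baseq, filter)
  list(admitted = tok == "ok", reason = tok)
}

#' Protocol strand of the fragment a read belongs to
#'
#' For unstranded libraries every read maps to `"both"`. For the dUTP
#' protocol (`fr-firststrand`) the second-in-pair read has the transcript's
#' orientation: read2 forward means the transcript is on the plus strand,
#' and a read1 (or single-end read, treated as read1) implies the opposite
#' of its own orientation. `fr-secondstrand` is the inverse convention.
#'
#' @param flag integer vector of SAM flags.
#' @param strandedness `"unstranded"`, `"fr-firststrand"` or
#'   `"fr-secondstrand"`.
#' @return character vector of `"plus"`, `"minus"` or `"both"`.
#' @export
fragment_strand <- function(flag, strandedness) {
  strandedness <- match.arg(strandedness, .STRAND_MODES)
  flag <- as.integer(flag)
  if (strandedness == "unstranded") return(rep("both", length(flag)))
  is_r1 <- bitwAnd(flag, .FLAG_READ1) > 0L
  is_r2 <- bitwAnd(flag, .FLAG_READ2) > 0L
  if (any(is_r1 & is_r2))
    stop("malformed record: flags mark a read as both first and second ",
         "in pair")
  rev <- bitwAnd(flag, .FLAG_REVERSE) > 0L
  # orientation of read2 (single-end/read1 implies the opposite of its own)
  r2_forward <- ifelse(is_r2, !rev, rev)
  plus <- if (strandedness == "fr-firststrand") r2_forward else !r2_forward
  ifelse(plus, "plus", "minus")
}

# 1-based query position aligned to reference position `pos`, or NA when the
# read has no aligned base there (deletion, skip, soft clip, out of span).
# Vectorized over reads; fast path for pure-match CIGARs.
.query_pos_at <- function(pos, read_start, cigar, seq_width) {
  qpos <- rep(NA_integer_, length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  if (any(simple)) {
    w <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
    qp <- pos - read_start[simple] + 1L
    qp[qp < 1L | qp > w] <- NA_integer_
    qpos[simple] <- qp
  }
  hard <- which(!simple)
  if (length(hard)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar[hard])
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar[hard])
    for (i in seq_along(hard)) {
      rpos <- read_start[hard[i]]
      q <- 1L
      found <- NA_integer_
      op <- ops[[i]]; ln <- lens[[i]]
      for (k in seq_along(op)) {
        consumes_ref <- op[k] %in% c("M", "=", "X", "D", "N")
        consumes_query <- op[k] %in% c("M", "=", "X", "I", "S")
        if (consumes_ref && pos < rpos + ln[k] && pos >= rpos) {
          if (op[k] %in% c("M", "=", "X")) found <- q + (pos - rpos)
          break
        }
        if (consumes_ref) rpos <- rpos + ln[k]
        if (consumes_query) q <- q + ln[k]
      }
      qpos[hard[i]] <- found
    }
  }
  qpos
}

#' Count alleles over SNPs from indexed BAM files
#'
#' Performs a filtered single-base pileup at every variant position, for one
#' BAM file per sample. Each admitted read overlapping the variant base
#' contributes exactly one count to
#' `counts[sample, variant, base, strand]`; when both mates of a pair
#' overlap the SNP the fragment is still counted once (the first-encountered
#' mate with a usable base wins). Reads whose alignment has no base at the
#' position (deletion, reference skip, soft clip) or a non-ACGT call
#' contribute nothing. For stranded libraries the `both` slice is
#' `plus + minus`.
#'
#' A per-sample counting report (admitted and rejected read tallies by
#' reason) is attached; retrieve it with [counting_report()].
#'
#' @param bam_paths character vector of BAM paths, one per sample; names are
#'   used as sample ids (basenames otherwise). Each BAM must be
#'   coordinate-sorted and indexed.
#' @param variants a variant table ([snp_variants()]) or a path accepted by
#'   [read_variants()].
#' @param filter a [count_filter()].
#' @param strandedness library protocol; see [fragment_strand()].
#' @return an `ase_dataset`.
#' @export
count_alleles <- function(bam_paths, variants, filter = count_filter(),
                          strandedness = "unstranded") {
  strandedness <- match.arg(strandedness, .STRAND_MODES)
  if (is.character(variants) && length(variants) == 1L && file.exists(variants))
    variants <- read_variants(variants)$variants
  validate_variants(variants)
  samples <- names(bam_paths)
  if (is.null(samples)) samples <- sub("\\.bam$", "", basename(bam_paths))
  for (b in bam_paths) {
    if (!file.exists(b)) stop("BAM file not found: ", b)
    if (!file.exists(paste0(b, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", b)))
      stop("BAM index (.bai) missing for: ", b)
  }

  nv <- nrow(variants)
  counts <- array(0L, c(length(samples), nv, 4L, 3L))
  report <- data.frame(sample = samples, admitted = 0L,
                       matrix(0L, length(samples), length(.REJECT_TOKENS),
                              dimnames = list(NULL, .REJECT_TOKENS)),
                       stringsAsFactors = FALSE)
  what <- c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual")

  for (i in seq_along(bam_paths)) {
    hdr <- Rsamtools::scanBamHeader(bam_paths[i])[[1]]$targets
    present <- variants$chrom %in% names(hdr)
    if (any(!present))
      warning(sum(!present), " variant(s) on chromosome(s) absent from ",
              basename(bam_paths[i]), "; zero counts recorded")
    vi <- which(present)
    if (!length(vi)) next
    which_gr <- GenomicRanges::GRanges(
      variants$chrom[vi], IRanges::IRanges(variants$pos[vi], variants$pos[vi]))
    param <- Rsamtools::ScanBamParam(which = which_gr, what = what)
    res <- Rsamtools::scanBam(bam_paths[i], param = param)
    for (r in seq_along(vi)) {
      j <- vi[r]
      rec <- res[[r]]
      if (!length(rec$flag)) next
      flag <- rec$flag
      seqs <- as.character(rec$seq)
      qpos <- .query_pos_at(variants$pos[j], rec$pos, rec$cigar, nchar(seqs))
      base <- rep(NA_character_, length(flag))
      baseq <- rep(NA_integer_, length(flag))
      has <- !is.na(qpos)
      if (any(has)) {
        base[has] <- substring(seqs[has], qpos[has], qpos[has])
        qual <- as.character(rec$qual)
        baseq[has] <- utf8ToInt_at(qual[has], qpos[has])
      }
      tok <- .admit_tokens(flag, rec$mapq, baseq, filter)
      usable <- tok == "ok" & has & base %in% .NT
      tok[tok == "ok" & !usable] <- "no_base"
      # once-per-fragment: among usable reads, first occurrence of each
      # query name wins (records arrive in coordinate order)
      first <- usable & !duplicated(ifelse(usable, rec$qname, NA),
                                    incomparables = NA)
      strand <- fragment_strand(flag[first], strandedness)
      nt_i <- match(base[first], .NT)
      st_i <- match(strand, .STRANDS)
      for (k in seq_along(nt_i))
        counts[i, j, nt_i[k], st_i[k]] <- counts[i, j, nt_i[k], st_i[k]] + 1L
      report$admitted[i] <- report$admitted[i] + sum(first)
      for (t in .REJECT_TOKENS)
        report[[t]][i] <- report[[t]][i] + sum(tok == t)
    }
  }
  ds <- build_dataset(counts, variants, samples, strandedness)
  attr(ds, "counting_report") <- report
  ds
}

# base quality (Phred) of character `at` within each quality string
utf8ToInt_at <- function(qual, at) {
  vapply(seq_along(qual),
         function(i) utf8ToInt(substring(qual[i], at[i], at[i])) - 33L,
         integer(1))
}

#' Per-sample admitted/rejected read tallies from [count_alleles()]
#'
#' @param ds an `ase_dataset` produced by [count_alleles()].
#' @return a `data.frame` with one row per sample, or `NULL` when the
#'   dataset was not produced by counting.
#' @export
counting_report <- function(ds) attr(ds, "counting_report")

#' Write the counting report as TSV
#' @param ds dataset from [count_alleles()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counting_report <- function(ds, path) {
  rep <- counting_report(ds)
  if (is.null(rep)) stop("dataset carries no counting report")
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
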