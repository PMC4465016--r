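# Text-level FASTA access used by the masking step. Masking must leave every
# non-variant byte untouched (including soft-mask case) and reproduce the
# input's exact line wrapping, so the file is processed line-by-line rather
# than through a sequence container that re-wraps or re-cases on write.
.read_fasta_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) stop("not a FASTA file (no '>' header): ", path)
  names <- sub("^>([^ \t]+).*$", "\\1", lines[hdr_idx])
  bounds <- c(hdr_idx, length(lines) + 1L)
  seqs <- lapply(seq_along(hdr_idx), function(i) {
    from <- hdr_idx[i] + 1L
    to <- bounds[i + 1L] - 1L
    if (from > to) character(0) else lines[from:to]
  })
  names(seqs) <- names
  list(lines = lines, hdr_idx = hdr_idx, names = names, seq_lines = seqs)
}

.fasta_lengths <- function(fa)
  vapply(fa$seq_lines, function(x) sum(nchar(x)), integer(1))

# replace bases at 1-based positions within one chromosome's line set
.mask_seq_lines <- function(seq_lines, positions, ch = "N") {
  widths <- nchar(seq_lines)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  line_of <- findInterval(positions, starts)
  for (i in seq_along(positions)) {
    li <- line_of[i]
    off <- positions[i] - starts[li] + 1L
    substr(seq_lines[li], off, off) <- ch
  }
  seq_lines
}

.variants_for_masking <- function(variants) {
  if (is.character(variants) && length(variants) == 1L) {
    if (grepl("\\.vcf(\\.gz)?$", variants, ignore.case = TRUE)) {
      # keep skip accounting; multi-allelic records still mask one position
      vcf <- vcfR::read.vcfR(variants, verbose = FALSE)
      fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
      ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
      alts <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
      snv <- !is.na(ref) & ref %in% .NT &
        vapply(alts, function(a) length(a) > 0 && all(a %in% .NT), logical(1))
      return(list(tab = data.frame(chrom = fix$CHROM[snv],
                                   pos = as.integer(fix$POS[snv]),
                                   stringsAsFactors = FALSE),
                  non_snv = sum(!snv)))
    }
    rv <- read_variants(variants)
    return(list(tab = rv$variants[, c("chrom", "pos")],
                non_snv = unname(rv$skipped["non_snv"])))
  }
  validate_variants(variants)
  list(tab = variants[, c("chrom", "pos")], non_snv = 0L)
}

#' N-mask known SNP positions in a reference FASTA
#'
#' Writes a copy of the reference in which every single-nucleotide variant
#' position is replaced by the ambiguity base `N` (uppercase). Everything
#' else — sequence order, line wrapping, headers, the case of unmasked
#' bases — is preserved byte-for-byte. Aligning reads to the masked
#' reference removes the penalty against the alternative allele and thereby
#' reduces reference-mapping bias.
#'
#' @param fasta_in input reference FASTA path.
#' @param variants variant table ([snp_variants()]), or a VCF/TSV path.
#'   Indels/MNVs are skipped and counted; multi-allelic SNV records mask
#'   their single position once.
#' @param fasta_out output FASTA path.
#' @return a `mask_report` list: `masked_positions` (per-chromosome counts),
#'   `records_applied`, `skipped_absent_chrom`, `skipped_out_of_bounds`,
#'   `skipped_non_snv`.
#' @examples
#' fa <- tempfile(fileext = ".fa"); out <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGT"), fa)
#' mask_reference(fa, snp_variants("chr1", 2L), out)
#' readLines(out)   # ">chr1" "ANGT"
#' @export
mask_reference <- function(fasta_in, variants, fasta_out) {
  fa <- .read_fasta_lines(fasta_in)
  vs <- .variants_for_masking(variants)
  tab <- vs$tab
  lens <- .fasta_lengths(fa)

  on_chrom <- tab$chrom %in% fa$names
  skipped_absent <- sum(!on_chrom)
  tab <- tab[on_chrom, , drop = FALSE]
  in_bounds <- tab$pos >= 1L & tab$pos <= lens[tab$chrom]
  skipped_oob <- sum(!in_bounds)
  if (skipped_oob)
    warning(skipped_oob, " variant(s) beyond chromosome length skipped")
  tab <- tab[in_bounds, , drop = FALSE]

  records_applied <- nrow(tab)
  masked <- integer(length(fa$names))
  names(masked) <- fa$names
  out_lines <- fa$lines
  bounds <- c(fa$hdr_idx, length(fa$lines) + 1L)
  for (i in seq_along(fa$names)) {
    pos <- unique(tab$pos[tab$chrom == fa$names[i]])
    masked[i] <- length(pos)
    if (!length(pos)) next
    from <- fa$hdr_idx[i] + 1L
    to <- bounds[i + 1L] - 1L
    out_lines[from:to] <- .mask_seq_lines(fa$lines[from:to], pos)
  }
  writeLines(out_lines, fasta_out)
  structure(list(masked_positions = masked,
                 records_applied = records_applied,
                 skipped_absent_chrom = skipped_absent,
                 skipped_out_of_bounds = skipped_oob,
                 skipped_non_snv = vs$non_snv),
            class = "mask_report")
}

#' @export
print.mask_report <- function(x, ...) {
  cat("mask_report: ", sum(x$masked_positions), " position(s) masked from ",
      x$records_applied, " record(s)\n", sep = "")
  for (ch in names(x$masked_positions))
    cat("  ", ch, ": ", x$masked_positions[[ch]], "\n", sep = "")
  cat("  skipped: ", x$skipped_absent_chrom, " absent-chromosome, ",
      x$skipped_out_of_bounds, " out-of-bounds, ",
      x$skipped_non_snv, " non-SNV\n", sep = "")
  invisible(x)
}

#' Write a masking report as TSV
#' @param report a `mask_report` from [mask_reference()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_report <- function(report, path) {
  stopifnot(inherits(report, "mask_report"))
  tab <- data.frame(chrom = names(report$masked_positions),
                    masked_positions = as.integer(report$masked_positions))
  extra <- data.frame(chrom = c("[records_applied]", "[skipped_absent_chrom]",
                                "[skipped_out_of_bounds]", "[skipped_non_snv]"),
                      masked_positions = c(report$records_applied,
                                           report$skipped_absent_chrom,
                                           report$skipped_out_of_bounds,
                                           report$skipped_non_snv))
  write.table(rbind(tab, extra), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Verify that a masked FASTA is exactly right
#'
#' Checks that every in-bounds SNV position is `N` in `fasta_out`, and that
#' every other position is byte-identical to `fasta_in`.
#'
#' @param fasta_in original FASTA.
#' @param fasta_out masked FASTA.
#' @param variants variant table or VCF/TSV path (as in [mask_reference()]).
#' @return `TRUE`/`FALSE` with attribute `discrepancies`, a `data.frame`
#'   of offending `chrom`, `pos`, `expected`, `observed`.
#' @export
verify_masking <- function(fasta_in, fasta_out, variants) {
  fa_in <- .read_fasta_lines(fasta_in)
  fa_out <- .read_fasta_lines(fasta_out)
  vs <- .variants_for_masking(variants)$tab
  disc <- list()
  if (!identical(fa_in$names, fa_out$names)) {
    disc[[length(disc) + 1L]] <- data.frame(
      chrom = "<layout>", pos = NA_integer_,
      expected = paste(fa_in$names, collapse = ","),
      observed = paste(fa_out$names, collapse = ","))
  } else {
    for (i in seq_along(fa_in$names)) {
      ch <- fa_in$names[i]
      s_in <- paste(fa_in$seq_lines[[i]], collapse = "")
      s_out <- paste(fa_out$seq_lines[[i]], collapse = "")
      if (nchar(s_in) != nchar(s_out)) {
        disc[[length(disc) + 1L]] <- data.frame(
          chrom = ch, pos = NA_integer_,
          expected = paste0("length ", nchar(s_in)),
          observed = paste0("length ", nchar(s_out)))
        next
      }
      want_n <- sort(unique(vs$pos[vs$chrom == ch &
                                     vs$pos >= 1L & vs$pos <= nchar(s_in)]))
      b_in <- strsplit(s_in, "", fixed = TRUE)[[1]]
      b_out <- strsplit(s_out, "", fixed = TRUE)[[1]]
      expect <- b_in
      if (length(want_n)) expect[want_n] <- "N"
      bad <- which(b_out != expect)
      if (length(bad))
        disc[[length(disc) + 1L]] <- data.frame(
          chrom = ch, pos = bad, expected = expect[bad],
          observed = b_out[bad])
    }
  }
  disc <- if (length(disc)) do.call(rbind, disc)
          else data.frame(chrom = character(), pos = integer(),
                          expected = character(), observed = character())
  structure(nrow(disc) == 0L, discrepancies = disc)
}
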