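#' Construct a validated SNP variant table
#'
#' A variant table is an ordinary `data.frame` with one row per
#' single-nucleotide variant and columns `chrom`, `pos` (1-based), `id`,
#' `ref`, `alt`. `ref`/`alt` may be `NA` when unknown; they can later be
#' resolved from counts with [resolve_alleles()].
#'
#' @param chrom character vector of sequence names.
#' @param pos integer vector of 1-based positions (single base each).
#' @param id variant identifiers; autogenerated (`chrom_pos`) when `NULL`.
#' @param ref,alt optional nucleotides in `A`,`C`,`G`,`T` (or `NA`).
#' @return a `data.frame` with columns `chrom, pos, id, ref, alt`.
#' @examples
#' snp_variants("chr1", c(100L, 200L), ref = c("A", "C"), alt = c("G", "T"))
#' @export
snp_variants <- function(chrom, pos, id = NULL, ref = NA_character_,
                         alt = NA_character_) {
  n <- max(length(chrom), length(pos))
  v <- data.frame(
    chrom = as.character(rep_len(chrom, n)),
    pos = as.integer(rep_len(pos, n)),
    id = if (is.null(id)) paste0(chrom, "_", pos) else as.character(rep_len(id, n)),
    ref = toupper(as.character(rep_len(ref, n))),
    alt = toupper(as.character(rep_len(alt, n))),
    stringsAsFactors = FALSE
  )
  validate_variants(v)
  v
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v))
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(v)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(v$pos)) || any(v$pos < 1L))
    stop("variant positions must be 1-based integers >= 1")
  bad_nt <- function(x) !is.na(x) & !(x %in% .NT)
  if (any(bad_nt(v$ref)) || any(bad_nt(v$alt)))
    stop("ref/alt alleles must be single nucleotides A, C, G or T (or NA); ",
         "only single-nucleotide variants are admitted")
  same <- !is.na(v$ref) & !is.na(v$alt) & v$ref == v$alt
  if (any(same))
    stop("ref and alt allele identical for variant(s): ",
         paste(v$id[same], collapse = ", "))
  if (anyDuplicated(v$id))
    stop("variant ids must be unique")
  invisible(v)
}

#' Read a variant list from VCF or TSV
#'
#' Accepts a VCF (plain or bgzipped; only biallelic SNVs are kept, everything
#' else is skipped and counted) or a headerless/headered 4-column TSV
#' (`chrom, pos, ref, alt`, optional 5th column `id`). Per-sample `GT` fields
#' in a VCF are returned as diploid genotype calls; phased separators (`|`)
#' are treated as unphased and `1/0` is normalized to `0/1`.
#'
#' @param path path to the variant file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return a list with elements `variants` (see [snp_variants()]),
#'   `genotypes` (sample x variant character matrix of `0/0`,`0/1`,`1/1` or
#'   `NA`; `NULL` when the file carries no samples) and `skipped`
#'   (named counts of discarded records).
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (format == "vcf") .read_variants_vcf(path) else .read_variants_tsv(path)
}

.read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  is_snv <- !is.na(ref) & !is.na(alt) &
    ref %in% .NT & alt %in% .NT
  multi <- !is.na(alt) & grepl(",", alt)
  keep <- which(is_snv & !multi)
  skipped <- c(non_snv = sum(!is_snv & !multi, na.rm = TRUE),
               multiallelic = sum(multi, na.rm = TRUE))
  id <- fix$ID[keep]
  id[is.na(id) | id == "."] <- paste0(fix$CHROM[keep], "_", fix$POS[keep])[is.na(id) | id == "."]
  v <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                  id = id, ref = ref[keep], alt = alt[keep],
                  stringsAsFactors = FALSE)
  # de-duplicate ids that collapse after the "." replacement
  if (anyDuplicated(v$id)) v$id <- make.unique(v$id, sep = "_")
  validate_variants(v)
  gt <- NULL
  if (ncol(vcf@gt) > 1L) {
    raw <- vcfR::extract.gt(vcf, element = "GT")
    raw <- raw[keep, , drop = FALSE]
    gt <- t(matrix(normalize_gt(raw), nrow = nrow(raw), ncol = ncol(raw)))
    dimnames(gt) <- list(colnames(vcf@gt)[-1L], v$id)
  }
  if (sum(skipped) > 0L)
    warning(sum(skipped), " non-SNV/multi-allelic record(s) skipped (of ",
            n_in, ")")
  list(variants = v, genotypes = gt, skipped = skipped)
}

.read_variants_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!has_header) {
    names(tab)[seq_len(min(5L, ncol(tab)))] <-
      c("chrom", "pos", "ref", "alt", "id")[seq_len(min(5L, ncol(tab)))]
  }
  if (!all(c("chrom", "pos") %in% names(tab)))
    stop("TSV variant list needs columns chrom, pos[, ref, alt, id]: ", path)
  if (is.null(tab$ref)) tab$ref <- NA_character_
  if (is.null(tab$alt)) tab$alt <- NA_character_
  n_in <- nrow(tab)
  ok <- (is.na(tab$ref) | toupper(tab$ref) %in% .NT) &
    (is.na(tab$alt) | toupper(tab$alt) %in% .NT)
  skipped <- c(non_snv = sum(!ok))
  tab <- tab[ok, , drop = FALSE]
  v <- snp_variants(tab$chrom, tab$pos, id = tab$id, ref = tab$ref, alt = tab$alt)
  if (skipped[["non_snv"]] > 0L)
    warning(skipped[["non_snv"]], " non-SNV record(s) skipped (of ", n_in, ")")
  list(variants = v, genotypes = NULL, skipped = skipped)
}

#' Normalize diploid GT strings
#'
#' `0|1`, `1/0`, `1|0` all become `0/1`; missing (`./.`, `.`) becomes `NA`.
#' Calls involving allele indices > 1 are set to `NA` (only biallelic SNVs
#' are modeled).
#'
#' @param gt character vector of VCF GT field values.
#' @return character vector of `0/0`, `0/1`, `1/1` or `NA`.
#' @export
normalize_gt <- function(gt) {
  gt <- gsub("|", "/", as.character(gt), fixed = TRUE)
  gt[gt %in% c(".", "./.", "", NA)] <- NA_character_
  gt[gt == "1/0"] <- "0/1"
  gt[!is.na(gt) & !gt %in% c("0/0", "0/1", "1/1")] <- NA_character_
  gt
}
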