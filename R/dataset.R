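#' Build a strand-aware allele-count dataset
#'
#' The central container of the package: an integer count tensor indexed
#' `[sample, variant, nucleotide (A,C,G,T), strand (plus,minus,both)]`
#' together with the variant table, sample identifiers, the library
#' strandedness, and optional per-sample phenotypes and per-cell genotypes.
#'
#' For stranded data (`fr-firststrand`/`fr-secondstrand`) the `both` slice is
#' recomputed as `plus + minus`, so strand additivity holds by construction.
#' For unstranded data all counts live on the `both` slice and the `plus` and
#' `minus` slices must be zero.
#'
#' @param counts integer array `samples x variants x 4 x 3`. A 3-dimensional
#'   `samples x variants x 4` array is also accepted for unstranded data and
#'   is placed on the `both` slice.
#' @param variants a variant table (see [snp_variants()]).
#' @param samples character vector of sample identifiers.
#' @param strandedness one of `"unstranded"`, `"fr-firststrand"`,
#'   `"fr-secondstrand"`.
#' @param phenotypes optional `data.frame` keyed by sample (rownames or a
#'   `sample` column); free-form, stored but not modeled.
#' @param genotypes optional sample x variant character matrix of provided
#'   diploid calls (`0/0`, `0/1`, `1/1`, `NA`); these override count-based
#'   inference everywhere genotypes are consumed.
#' @return an object of class `ase_dataset`.
#' @examples
#' v <- snp_variants("chr1", 100L, ref = "A", alt = "G")
#' cnt <- array(0L, c(1, 1, 4, 3), dimnames = list("s1", v$id,
#'   c("A", "C", "G", "T"), c("plus", "minus", "both")))
#' cnt["s1", 1, "A", "both"] <- 3L
#' cnt["s1", 1, "G", "both"] <- 1L
#' ds <- build_dataset(cnt, v, "s1", "unstranded")
#' allele_fractions(ds)                      # 3 / (3 + 1) = 0.75
#' @export
build_dataset <- function(counts, variants, samples,
                          strandedness = c("unstranded", "fr-firststrand",
                                           "fr-secondstrand"),
                          phenotypes = NULL, genotypes = NULL) {
  if (is.character(strandedness) && length(strandedness) == 1L &&
      !strandedness %in% .STRAND_MODES)
    stop("unknown strandedness: '", strandedness, "' (expected one of ",
         paste(.STRAND_MODES, collapse = ", "), ")")
  strandedness <- match.arg(strandedness)
  validate_variants(variants)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample ids must be unique")

  if (length(dim(counts)) == 3L) {
    if (strandedness != "unstranded")
      stop("3-d count array only valid for unstranded data")
    full <- array(0L, c(dim(counts), 3L))
    full[, , , 3L] <- counts
    counts <- full
  }
  d <- dim(counts)
  if (length(d) != 4L || d[3] != 4L || d[4] != 3L ||
      d[1] != length(samples) || d[2] != nrow(variants))
    stop("count tensor must be samples x variants x 4 x 3 (got ",
         paste(d, collapse = " x "), " for ", length(samples), " sample(s), ",
         nrow(variants), " variant(s))")
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"

  if (strandedness == "unstranded") {
    if (any(counts[, , , 1:2] != 0L))
      stop("unstranded data must carry all counts on the 'both' slice ",
           "(plus/minus slices nonzero)")
  } else {
    counts[, , , 3L] <- counts[, , , 1L] + counts[, , , 2L]
  }
  dimnames(counts) <- list(samples, variants$id, .NT, .STRANDS)

  if (!is.null(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes)
    if (!is.null(phenotypes$sample)) rownames(phenotypes) <- phenotypes$sample
    if (!all(samples %in% rownames(phenotypes)))
      stop("phenotype table missing sample(s): ",
           paste(setdiff(samples, rownames(phenotypes)), collapse = ", "))
    phenotypes <- phenotypes[samples, , drop = FALSE]
  }
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    if (!identical(dim(genotypes), c(length(samples), nrow(variants))))
      stop("genotype matrix must be samples x variants")
    genotypes[] <- normalize_gt(genotypes)
    dimnames(genotypes) <- list(samples, variants$id)
  }

  structure(
    list(counts = counts, variants = variants, samples = samples,
         strandedness = strandedness, phenotypes = phenotypes,
         genotypes = genotypes),
    class = "ase_dataset"
  )
}

#' @export
print.ase_dataset <- function(x, ...) {
  cat("ase_dataset: ", length(x$samples), " sample(s) x ", nrow(x$variants),
      " variant(s), ", x$strandedness, "\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$variants$chrom), collapse = ", "),
      "\n", sep = "")
  cat("  total counts (both strand): ", sum(x$counts[, , , "both"]),
      "\n", sep = "")
  if (!is.null(x$genotypes)) cat("  provided genotypes: yes\n")
  if (!is.null(x$phenotypes))
    cat("  phenotypes: ", paste(names(x$phenotypes), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.ase_dataset <- function(object, ...) {
  depth <- apply(object$counts[, , , "both", drop = FALSE], c(1, 2), sum)
  cat("ase_dataset summary\n")
  print(object)
  cat("  per-cell depth: min ", min(depth), ", median ",
      stats::median(depth), ", max ", max(depth), "\n", sep = "")
  invisible(object)
}

n_samples <- function(ds) length(ds$samples)
n_variants <- function(ds) nrow(ds$variants)

.parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    return(region)
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("region must be 'chrom:start-end' (1-based, closed): ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Subset a dataset by genomic region and/or samples
#'
#' The region is a 1-based fully-closed interval (`chrom:start-end`); a
#' variant at `pos` is retained when `start <= pos <= end` on that
#' chromosome. Original variant and sample order is preserved. An empty
#' result is a valid empty dataset, not an error.
#'
#' @param ds an `ase_dataset`.
#' @param region optional `"chrom:start-end"` string or
#'   `list(chrom=, start=, end=)`.
#' @param samples optional character vector of sample ids to keep; unknown
#'   ids are an error.
#' @return an `ase_dataset`.
#' @export
subset_dataset <- function(ds, region = NULL, samples = NULL) {
  stopifnot(inherits(ds, "ase_dataset"))
  vi <- seq_len(n_variants(ds))
  if (!is.null(region)) {
    r <- .parse_region(region)
    vi <- which(ds$variants$chrom == r$chrom &
                  ds$variants$pos >= r$start & ds$variants$pos <= r$end)
  }
  si <- seq_len(n_samples(ds))
  if (!is.null(samples)) {
    unknown <- setdiff(samples, ds$samples)
    if (length(unknown))
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    si <- which(ds$samples %in% samples)
  }
  build_dataset(
    counts = ds$counts[si, vi, , , drop = FALSE],
    variants = ds$variants[vi, , drop = FALSE],
    samples = ds$samples[si],
    strandedness = ds$strandedness,
    phenotypes = if (is.null(ds$phenotypes)) NULL
                 else ds$phenotypes[si, , drop = FALSE],
    genotypes = if (is.null(ds$genotypes)) NULL
                else ds$genotypes[si, vi, drop = FALSE]
  )
}

#' Rank the two most-observed alleles per variant
#'
#' Variants that carry `ref`/`alt` metadata return it unchanged. Otherwise
#' nucleotides are ranked by total count over all samples on the `both`
#' strand and the top two are returned, ties broken alphabetically. A
#' zero-count variant returns `(A, C)` and is flagged low-confidence.
#'
#' @param ds an `ase_dataset`.
#' @return `data.frame` with columns `id, ref, alt, source`
#'   (`"given"`/`"counts"`), `low_confidence`.
#' @export
top_alleles <- function(ds) {
  stopifnot(inherits(ds, "ase_dataset"))
  nv <- n_variants(ds)
  out <- data.frame(id = ds$variants$id, ref = NA_character_,
                    alt = NA_character_, source = "counts",
                    low_confidence = FALSE, stringsAsFactors = FALSE)
  totals <- apply(ds$counts[, , , "both", drop = FALSE], c(2, 3), sum)
  # totals: variants x 4 (drop sample+strand axes)
  for (j in seq_len(nv)) {
    given_ref <- ds$variants$ref[j]
    given_alt <- ds$variants$alt[j]
    if (!is.na(given_ref) && !is.na(given_alt)) {
      out$ref[j] <- given_ref
      out$alt[j] <- given_alt
      out$source[j] <- "given"
      next
    }
    tot <- totals[j, ]
    ord <- order(-tot, .NT)   # descending count, alphabetical tie-break
    out$ref[j] <- .NT[ord[1]]
    out$alt[j] <- .NT[ord[2]]
    out$low_confidence[j] <- sum(tot) == 0L
  }
  out
}

#' Fill unresolved ref/alt alleles from observed counts
#'
#' @param ds an `ase_dataset`.
#' @return the dataset with `variants$ref`/`variants$alt` fully populated.
#' @export
resolve_alleles <- function(ds) {
  ta <- top_alleles(ds)
  ds$variants$ref <- ta$ref
  ds$variants$alt <- ta$alt
  ds
}

.require_resolved <- function(ds) {
  if (anyNA(ds$variants$ref) || anyNA(ds$variants$alt))
    stop("ref/alt alleles unresolved for some variants; call ",
         "resolve_alleles() (or top_alleles()) first")
}

# sample x variant count matrix for one allele column ("ref" or "alt")
.allele_count_matrix <- function(ds, allele, strand) {
  nt_idx <- match(ds$variants[[allele]], .NT)
  s_idx <- match(strand, .STRANDS)
  m <- matrix(0L, n_samples(ds), n_variants(ds),
              dimnames = list(ds$samples, ds$variants$id))
  for (j in seq_len(n_variants(ds)))
    m[, j] <- ds$counts[, j, nt_idx[j], s_idx]
  m
}

#' Reference-allele fractions per sample and variant
#'
#' `fraction = ref / (ref + alt)` on the chosen strand; counts of the other
#' two nucleotides are ignored. Cells with `ref + alt < min_depth` are `NA`
#' (never 0 or 1).
#'
#' @param ds an `ase_dataset` with resolved ref/alt alleles.
#' @param strand `"plus"`, `"minus"` or `"both"`.
#' @param min_depth minimum `ref + alt` depth for a non-missing fraction.
#' @return numeric sample x variant matrix with attribute `min_depth`.
#' @export
allele_fractions <- function(ds, strand = "both", min_depth = 1L) {
  stopifnot(inherits(ds, "ase_dataset"), min_depth >= 1L)
  strand <- match.arg(strand, .STRANDS)
  .require_resolved(ds)
  k <- .allele_count_matrix(ds, "ref", strand)
  a <- .allele_count_matrix(ds, "alt", strand)
  n <- k + a
  f <- k / n
  f[n < min_depth] <- NA_real_
  attr(f, "min_depth") <- as.integer(min_depth)
  f
}

#' Infer diploid genotypes from allele counts
#'
#' A cell is called heterozygous when its `ref + alt` depth is at least
#' `min_depth` and the minor-of-(ref, alt) fraction is at least `het_low`;
#' homozygous for the major allele when the minor fraction is below
#' `het_low`; no-call (`NA`) under the depth gate. Provided genotypes
#' (`ds$genotypes`) always override inferred calls.
#'
#' @param ds an `ase_dataset` with resolved ref/alt alleles.
#' @param min_depth depth gate for calling (default 10).
#' @param het_low minimum minor-allele fraction for a het call (default 0.10).
#' @param strand strand slice used for counting (default `"both"`).
#' @return character sample x variant matrix of `0/0`, `0/1`, `1/1`, `NA`.
#' @export
infer_genotypes <- function(ds, min_depth = 10L, het_low = 0.10,
                            strand = "both") {
  stopifnot(inherits(ds, "ase_dataset"))
  .require_resolved(ds)
  k <- .allele_count_matrix(ds, "ref", strand)
  a <- .allele_count_matrix(ds, "alt", strand)
  n <- k + a
  minor_frac <- pmin(k, a) / n
  gt <- matrix(NA_character_, n_samples(ds), n_variants(ds),
               dimnames = list(ds$samples, ds$variants$id))
  called <- n >= min_depth
  het <- called & minor_frac >= het_low
  hom_ref <- called & !het & k >= a
  hom_alt <- called & !het & k < a
  gt[het] <- "0/1"
  gt[hom_ref] <- "0/0"
  gt[hom_alt] <- "1/1"
  if (!is.null(ds$genotypes)) {
    prov <- ds$genotypes
    gt[!is.na(prov)] <- prov[!is.na(prov)]
  }
  gt
}

#' Minor-allele frequency across samples
#'
#' From diploid genotype calls: with `f = (2 * hom_ref + het) / (2 * called)`
#' the reference-allele frequency over called samples, `MAF = min(f, 1 - f)`.
#' No-calls are excluded from the denominator; a variant with zero called
#' samples gets `NA`.
#'
#' @param ds an `ase_dataset`.
#' @param genotypes optional sample x variant genotype matrix; defaults to
#'   [infer_genotypes()] (which itself honors provided genotypes).
#' @return named numeric vector, one MAF in `[0, 0.5]` (or `NA`) per variant.
#' @export
maf <- function(ds, genotypes = NULL) {
  stopifnot(inherits(ds, "ase_dataset"))
  if (is.null(genotypes)) genotypes <- infer_genotypes(resolve_alleles(ds))
  hom_ref <- colSums(genotypes == "0/0", na.rm = TRUE)
  het <- colSums(genotypes == "0/1", na.rm = TRUE)
  called <- colSums(!is.na(genotypes))
  f <- (2 * hom_ref + het) / (2 * called)
  f[called == 0L] <- NA_real_
  setNames(pmin(f, 1 - f), ds$variants$id)
}

#' Keep variants with MAF strictly above a threshold
#'
#' @param ds an `ase_dataset`.
#' @param threshold MAF cutoff; variants with `MAF > threshold` are kept
#'   (missing MAF drops the variant).
#' @param genotypes optional genotype matrix passed to [maf()].
#' @return an `ase_dataset`.
#' @export
maf_filter <- function(ds, threshold = 0.1, genotypes = NULL) {
  m <- maf(ds, genotypes)
  keep <- !is.na(m) & m > threshold
  vi <- which(keep)
  build_dataset(ds$counts[, vi, , , drop = FALSE],
                ds$variants[vi, , drop = FALSE], ds$samples, ds$strandedness,
                ds$phenotypes,
                if (is.null(ds$genotypes)) NULL
                else ds$genotypes[, vi, drop = FALSE])
}

#' Serialize a dataset to wide TSV
#'
#' One row per variant: `chrom, pos, id, ref, alt`, then one count column per
#' `sample x nucleotide x strand` named `<sample>.<nt>.<strand>`, then one
#' `<sample>.gt` column per sample when provided genotypes exist.
#' Strandedness and phenotypes are kept in `#`-prefixed header lines, so the
#' round trip through [read_dataset_tsv()] is lossless.
#'
#' @param ds an `ase_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "ase_dataset"))
  hdr <- c("#asekit_dataset\tv1",
           paste0("#strandedness\t", ds$strandedness))
  if (!is.null(ds$phenotypes)) {
    for (key in names(ds$phenotypes))
      hdr <- c(hdr, paste0("#phenotype\t", key, "\t",
                           paste(ds$phenotypes[[key]], collapse = "\t")))
  }
  tab <- ds$variants[, c("chrom", "pos", "id", "ref", "alt")]
  for (s in ds$samples)
    for (nt in .NT)
      for (st in .STRANDS)
        tab[[paste(s, nt, st, sep = ".")]] <- ds$counts[s, , nt, st]
  if (!is.null(ds$genotypes))
    for (s in ds$samples) tab[[paste0(s, ".gt")]] <- ds$genotypes[s, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "."))
  invisible(path)
}

#' Read a dataset written by [write_dataset_tsv()]
#'
#' @param path TSV file.
#' @return an `ase_dataset`.
#' @export
read_dataset_tsv <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  strandedness <- "unstranded"
  phenotypes <- list()
  for (h in hdr) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1]]
    if (f[1] == "#strandedness") strandedness <- f[2]
    if (f[1] == "#phenotype") phenotypes[[f[2]]] <- f[-(1:2)]
  }
  tab <- read.delim(text = body, stringsAsFactors = FALSE, na.strings = ".",
                    check.names = FALSE)
  v <- snp_variants(tab$chrom, tab$pos, id = tab$id, ref = tab$ref,
                    alt = tab$alt)
  count_cols <- grep("^.+\\.[ACGT]\\.(plus|minus|both)$", names(tab),
                     value = TRUE)
  samples <- unique(sub("\\.[ACGT]\\.(plus|minus|both)$", "", count_cols))
  counts <- array(0L, c(length(samples), nrow(v), 4L, 3L))
  for (i in seq_along(samples))
    for (nt_i in 1:4)
      for (st_i in 1:3) {
        col <- paste(samples[i], .NT[nt_i], .STRANDS[st_i], sep = ".")
        if (col %in% names(tab)) counts[i, , nt_i, st_i] <- tab[[col]]
      }
  gt_cols <- paste0(samples, ".gt")
  genotypes <- NULL
  if (all(gt_cols %in% names(tab))) {
    genotypes <- t(as.matrix(tab[, gt_cols, drop = FALSE]))
    dimnames(genotypes) <- list(samples, v$id)
  }
  ph <- NULL
  if (length(phenotypes)) {
    ph <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
    rownames(ph) <- samples
  }
  build_dataset(counts, v, samples, strandedness, ph, genotypes)
}
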