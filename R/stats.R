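#' Two-sided exact binomial p-value (minimum-likelihood method)
#'
#' For observed `k` successes out of `n` trials under success probability
#' `p0`, the p-value is the sum of `P(X = i)` over all outcomes `i` whose
#' probability does not exceed `P(X = k)` (with a 1e-7 relative tolerance
#' for ties), `X ~ Binomial(n, p0)`. This is the standard definition of the
#' two-sided exact test.
#'
#' @param k,n,p0 vectors (recycled) of successes, trials, null probability.
#' @return numeric vector of p-values in `[0, 1]`.
#' @examples
#' binom_pvalue(10, 10, 0.5)   # 2 / 1024
#' @export
binom_pvalue <- function(k, n, p0 = 0.5) {
  len <- max(length(k), length(n), length(p0))
  k <- rep_len(as.integer(k), len)
  n <- rep_len(as.integer(n), len)
  p0 <- rep_len(p0, len)
  out <- rep(NA_real_, len)
  for (i in seq_len(len)) {
    if (is.na(k[i]) || is.na(n[i]) || n[i] < 1L) next
    d <- dbinom(0:n[i], n[i], p0[i])
    out[i] <- min(1, sum(d[d <= d[k[i] + 1L] * (1 + 1e-7)]))
  }
  out
}

# normalize an expected-ratio spec (scalar / per-variant vector /
# sample x variant matrix) to a full sample x variant matrix, validating
# the open (0,1) bound.
.expected_matrix <- function(expected, ds) {
  ns <- n_samples(ds); nv <- n_variants(ds)
  if (is.matrix(expected)) {
    if (!identical(dim(expected), c(ns, nv)))
      stop("expected-ratio matrix must be samples x variants")
    e <- expected
  } else if (length(expected) == 1L) {
    e <- matrix(expected, ns, nv)
  } else if (length(expected) == nv) {
    if (!is.null(names(expected)) &&
        !identical(names(expected), ds$variants$id))
      expected <- expected[ds$variants$id]
    e <- matrix(rep(expected, each = ns), ns, nv)
  } else {
    stop("expected must be a scalar, a per-variant vector, or a ",
         "samples x variants matrix")
  }
  if (anyNA(e) || any(e <= 0) || any(e >= 1))
    stop("expected allele ratios must lie strictly between 0 and 1")
  dimnames(e) <- list(ds$samples, ds$variants$id)
  e
}

.test_matrix <- function(ds, expected, strand, min_depth, het_only, method) {
  stopifnot(inherits(ds, "ase_dataset"), min_depth >= 1L)
  strand <- match.arg(strand, .STRANDS)
  .require_resolved(ds)
  e <- .expected_matrix(expected, ds)
  k <- .allele_count_matrix(ds, "ref", strand)
  a <- .allele_count_matrix(ds, "alt", strand)
  total <- apply(ds$counts[, , , match(strand, .STRANDS), drop = FALSE],
                 c(1, 2), sum)
  n <- k + a
  other <- total - n
  est <- k / n
  est[n == 0L] <- NA_real_
  testable <- n >= min_depth
  if (het_only) {
    gt <- infer_genotypes(ds)
    testable <- testable & !is.na(gt) & gt == "0/1"
  }
  p <- matrix(NA_real_, nrow(k), ncol(k), dimnames = dimnames(k))
  stat <- p
  idx <- which(testable)
  if (length(idx)) {
    if (method == "binom") {
      p[idx] <- binom_pvalue(k[idx], n[idx], e[idx])
    } else {
      exp_ref <- n[idx] * e[idx]
      exp_alt <- n[idx] * (1 - e[idx])
      x2 <- (k[idx] - exp_ref)^2 / exp_ref +
        ((n[idx] - k[idx]) - exp_alt)^2 / exp_alt
      stat[idx] <- x2
      p[idx] <- pchisq(x2, df = 1, lower.tail = FALSE)
    }
  }
  structure(
    list(p_values = p, estimates = est, statistic = stat,
         ref_counts = k, alt_counts = a, other_counts = other,
         method = method, expected = e, strand = strand,
         min_depth = as.integer(min_depth), het_only = het_only,
         samples = ds$samples, variants = ds$variants,
         p_adjusted = NULL, adjust_method = "none"),
    class = "ase_test"
  )
}

#' Exact binomial test of allelic imbalance per SNP and sample
#'
#' For every cell with reference count `k` and informative depth
#' `n = ref + alt >= min_depth` (and, when `het_only`, a heterozygous
#' genotype), computes the two-sided exact binomial p-value of `k` out of
#' `n` under the cell's expected reference fraction (default 1:1, i.e. 0.5).
#' Counts on the two non-(ref, alt) nucleotides are excluded from `n` and
#' reported separately in `other_counts` as a sequencing-error diagnostic.
#' Gated cells are `NA`, never 1.
#'
#' @param ds an `ase_dataset` with resolved ref/alt alleles.
#' @param expected expected reference-allele fraction: scalar, per-variant
#'   vector (e.g. from [set_expected_from_counts()]), or sample x variant
#'   matrix; each entry strictly in (0, 1).
#' @param strand which strand slice to test.
#' @param min_depth minimum informative depth (default 10).
#' @param het_only test only heterozygous cells (default `TRUE`; provided
#'   genotypes override inference).
#' @return an `ase_test` with matrices `p_values`, `estimates`,
#'   `ref_counts`, `alt_counts`, `other_counts`.
#' @export
binom_test_matrix <- function(ds, expected = 0.5, strand = "both",
                              min_depth = 10L, het_only = TRUE) {
  .test_matrix(ds, expected, strand, min_depth, het_only, "binom")
}

#' Chi-square goodness-of-fit test of allelic imbalance
#'
#' Same gating and interface as [binom_test_matrix()], but each cell is
#' tested with the 1-df goodness-of-fit statistic
#' `X^2 = (k - n p0)^2 / (n p0) + ((n - k) - n (1 - p0))^2 / (n (1 - p0))`
#' without continuity correction, upper-tail chi-square p-value.
#'
#' @inheritParams binom_test_matrix
#' @return an `ase_test`; `statistic` holds the X^2 values.
#' @export
chisq_test_matrix <- function(ds, expected = 0.5, strand = "both",
                              min_depth = 10L, het_only = TRUE) {
  .test_matrix(ds, expected, strand, min_depth, het_only, "chisq")
}

#' @export
print.ase_test <- function(x, ...) {
  ntest <- sum(!is.na(x$p_values))
  cat("ase_test (", x$method, "): ", length(x$samples), " sample(s) x ",
      nrow(x$variants), " variant(s), strand=", x$strand,
      ", min_depth=", x$min_depth, ", het_only=", x$het_only, "\n", sep = "")
  cat("  tested cells: ", ntest, "; adjust: ", x$adjust_method, "\n", sep = "")
  if (ntest) {
    pv <- x$p_values[!is.na(x$p_values)]
    cat("  p-values: min ", format(min(pv), digits = 3), ", median ",
        format(stats::median(pv), digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Multiple-testing adjustment of a test-result matrix
#'
#' Adjustment is applied jointly over all non-missing cells of the p-value
#' matrix; missing cells stay missing. `"none"` is the identity.
#'
#' @param result an `ase_test`.
#' @param method `"none"`, `"benjamini-hochberg"` or `"bonferroni"`.
#' @return the `ase_test` with `p_adjusted` filled in.
#' @export
adjust_pvalues <- function(result,
                           method = c("none", "benjamini-hochberg",
                                      "bonferroni")) {
  stopifnot(inherits(result, "ase_test"))
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("none", "benjamini-hochberg", "bonferroni"))
    stop("unknown adjustment method: '", method, "'")
  method <- match.arg(method)
  p <- result$p_values
  adj <- p
  ok <- !is.na(p)
  adj[ok] <- switch(method,
    "none" = p[ok],
    "benjamini-hochberg" = p.adjust(p[ok], method = "BH"),
    "bonferroni" = p.adjust(p[ok], method = "bonferroni"))
  result$p_adjusted <- adj
  result$adjust_method <- method
  result
}

#' Estimate expected allele ratios from null material
#'
#' Given counts from material with known 1:1 truth (simulated reads with
#' equal allele representation, or DNA), the per-variant expected reference
#' fraction is the ref/(ref+alt) fraction pooled across samples, clamped to
#' `[0.05, 0.95]`. Variants whose pooled depth is below `min_depth` fall
#' back to 0.5. Feeding the result to [binom_test_matrix()] as `expected`
#' adjusts the test for reference-mapping bias.
#'
#' @param null_ds an `ase_dataset` of null (1:1 truth) counts with resolved
#'   ref/alt alleles.
#' @param min_depth minimum pooled depth (default 10).
#' @param strand strand slice to pool (default `"both"`).
#' @return named numeric vector of expected reference fractions per variant.
#' @export
set_expected_from_counts <- function(null_ds, min_depth = 10L,
                                     strand = "both") {
  stopifnot(inherits(null_ds, "ase_dataset"))
  .require_resolved(null_ds)
  k <- colSums(.allele_count_matrix(null_ds, "ref", strand))
  a <- colSums(.allele_count_matrix(null_ds, "alt", strand))
  n <- k + a
  e <- ifelse(n >= min_depth, pmin(pmax(k / n, 0.05), 0.95), 0.5)
  setNames(e, null_ds$variants$id)
}

#' Export test results as long-format TSV
#'
#' One row per sample x variant cell with columns `sample, chrom, pos, id,
#' ref, alt, strand, ref_count, alt_count, other_count, fraction, expected,
#' p_value, p_adjusted, method`. Missing values are written as `NA`.
#'
#' @param result an `ase_test`.
#' @param path output file.
#' @param drop_untested drop cells whose p-value is missing (default `TRUE`).
#' @return the exported `data.frame`, invisibly.
#' @export
write_results_tsv <- function(result, path, drop_untested = TRUE) {
  stopifnot(inherits(result, "ase_test"))
  v <- result$variants
  ns <- length(result$samples); nv <- nrow(v)
  long <- data.frame(
    sample = rep(result$samples, times = nv),
    chrom = rep(v$chrom, each = ns),
    pos = rep(v$pos, each = ns),
    id = rep(v$id, each = ns),
    ref = rep(v$ref, each = ns),
    alt = rep(v$alt, each = ns),
    strand = result$strand,
    ref_count = as.vector(result$ref_counts),
    alt_count = as.vector(result$alt_counts),
    other_count = as.vector(result$other_counts),
    fraction = as.vector(result$estimates),
    expected = as.vector(result$expected),
    p_value = as.vector(result$p_values),
    p_adjusted = if (is.null(result$p_adjusted)) NA_real_
                 else as.vector(result$p_adjusted),
    method = result$method,
    stringsAsFactors = FALSE
  )
  if (drop_untested) long <- long[!is.na(long$p_value), , drop = FALSE]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(long)
}
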