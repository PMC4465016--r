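# default nucleotide palette; override with options(asekit.palette = ...)
.nt_palette <- function() {
  pal <- getOption("asekit.palette",
                   c(A = "#1b9e77", C = "#7570b3", G = "#d95f02",
                     T = "#e7298a"))
  pal[.NT]
}

.open_device <- function(out, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(out))
  switch(ext,
    "png" = png(out, width = width, height = height, units = "in", res = 150),
    "svg" = svg(out, width = width, height = height),
    "pdf" = pdf(out, width = width, height = height),
    stop("unsupported image format '.", ext, "' (use .png, .svg or .pdf)"))
}

.variant_index <- function(ds, variant_id) {
  j <- match(variant_id, ds$variants$id)
  if (is.na(j)) stop("unknown variant id: ", variant_id)
  j
}

#' Format a p-value for plot annotation
#'
#' Fixed three decimals for `p >= 0.001` (so 0.001953125 renders as
#' `"0.002"`), one-significant-digit scientific notation below, and `"nd"`
#' for missing values.
#'
#' @param p numeric vector of p-values (may contain `NA`).
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  out <- rep("nd", length(p))
  ok <- !is.na(p)
  big <- ok & p >= 0.001
  out[big] <- sprintf("%.3f", p[big])
  small <- ok & p < 0.001
  out[small] <- sprintf("%.0e", p[small])
  out
}

#' Per-sample allele barplot for one SNP
#'
#' Count mode draws one group of four nucleotide bars per sample; fraction
#' mode draws one reference-fraction bar per sample with a horizontal guide
#' line at the expected ratio (1:1 by default). The plot is written to
#' `out` (`.png`, `.svg` or `.pdf`); `.svg` output is byte-deterministic
#' for identical input.
#'
#' @param ds an `ase_dataset`.
#' @param variant_id id of the variant to draw.
#' @param mode `"count"` or `"fraction"`.
#' @param out output image path.
#' @param strand strand slice to draw (default `"both"`).
#' @param expected guide-line height in fraction mode (default 0.5).
#' @param min_depth depth gate for fraction mode (under-depth cells are
#'   drawn as missing).
#' @return invisibly, a layout list describing the drawn structure
#'   (`type`, `mode`, `samples`, `heights`/`fractions`, `guide`).
#' @export
barplot_snp <- function(ds, variant_id, mode = c("count", "fraction"), out,
                        strand = "both", expected = 0.5, min_depth = 1L) {
  stopifnot(inherits(ds, "ase_dataset"))
  mode <- match.arg(mode)
  j <- .variant_index(ds, variant_id)
  ns <- n_samples(ds)
  pal <- .nt_palette()
  .open_device(out)
  on.exit(dev.off())
  if (mode == "count") {
    h <- t(ds$counts[, j, , match(strand, .STRANDS), drop = TRUE])
    if (ns == 1L) h <- matrix(ds$counts[1, j, , match(strand, .STRANDS)],
                              ncol = 1L)
    dimnames(h) <- list(.NT, ds$samples)
    graphics::barplot(h, beside = TRUE, col = pal, border = NA,
                      ylab = "allele count", main = variant_id,
                      names.arg = ds$samples, las = 2)
    graphics::legend("topright", legend = .NT, fill = pal, bty = "n")
    layout <- list(type = "barplot", mode = mode, variant = variant_id,
                   samples = ds$samples, heights = h, guide = NA_real_)
  } else {
    f <- allele_fractions(resolve_alleles(ds), strand = strand,
                          min_depth = min_depth)[, j]
    bh <- ifelse(is.na(f), 0, f)
    bp <- graphics::barplot(bh, col = ifelse(is.na(f), "grey85", "grey40"),
                            border = NA, ylim = c(0, 1),
                            ylab = "reference-allele fraction",
                            main = variant_id, names.arg = ds$samples, las = 2)
    abline(h = expected, lwd = 2)
    if (any(is.na(f)))
      text(bp[is.na(f)], 0.02, "nd", cex = 0.8)
    layout <- list(type = "barplot", mode = mode, variant = variant_id,
                   samples = ds$samples, fractions = f, guide = expected)
  }
  invisible(layout)
}

#' Dual-strand allele barplot with per-sample p-values
#'
#' For stranded data only: plus-strand allele counts are drawn upward,
#' minus-strand counts downward, one group per sample in dataset order,
#' with per-sample test p-values annotated beneath the bars (see
#' [format_pvalue()]; missing values print as `"nd"`). Unstranded datasets
#' are refused — use [barplot_snp()] for those.
#'
#' @param ds a stranded `ase_dataset`.
#' @param variant_id variant to draw.
#' @param test_plus,test_minus optional `ase_test` results for the plus and
#'   minus strands; their p-values for `variant_id` are the annotations.
#' @param out output image path.
#' @return invisibly, a layout list (`samples`, `plus`/`minus` count
#'   matrices, `p_plus`, `p_minus`, annotation strings).
#' @export
dual_strand_barplot <- function(ds, variant_id, test_plus = NULL,
                                test_minus = NULL, out) {
  stopifnot(inherits(ds, "ase_dataset"))
  if (ds$strandedness == "unstranded")
    stop("dual_strand_barplot needs stranded data; use barplot_snp() for ",
         "unstranded datasets")
  j <- .variant_index(ds, variant_id)
  ns <- n_samples(ds)
  up <- matrix(ds$counts[, j, , 1L], nrow = ns,
               dimnames = list(ds$samples, .NT))
  dn <- matrix(ds$counts[, j, , 2L], nrow = ns,
               dimnames = list(ds$samples, .NT))
  p_up <- if (is.null(test_plus)) rep(NA_real_, ns)
          else test_plus$p_values[, .variant_index(ds, variant_id)]
  p_dn <- if (is.null(test_minus)) rep(NA_real_, ns)
          else test_minus$p_values[, .variant_index(ds, variant_id)]
  lab_up <- format_pvalue(p_up)
  lab_dn <- format_pvalue(p_dn)

  pal <- .nt_palette()
  top <- max(1L, max(up))
  bot <- max(1L, max(dn))
  group_w <- 5
  .open_device(out, width = max(7, 1.2 * ns), height = 5)
  on.exit(dev.off())
  par(mar = c(6, 4, 3, 1))
  plot(NA, xlim = c(0, ns * group_w), ylim = c(-1.25 * bot, 1.1 * top),
       xlab = "", ylab = "allele count (+ up / - down)", xaxt = "n",
       main = variant_id)
  abline(h = 0)
  for (i in seq_len(ns)) {
    x0 <- (i - 1) * group_w
    for (b in 1:4) {
      rect(x0 + b - 1 + 0.1, 0, x0 + b - 0.1, up[i, b],
           col = pal[b], border = NA)
      rect(x0 + b - 1 + 0.1, -dn[i, b], x0 + b - 0.1, 0,
           col = pal[b], border = NA)
    }
    text(x0 + 2, -1.12 * bot, lab_up[i], cex = 0.8)
    if (!all(is.na(p_dn))) text(x0 + 2, -1.22 * bot, lab_dn[i], cex = 0.7)
  }
  axis(1, at = (seq_len(ns) - 0.5) * group_w - 0.5, labels = ds$samples,
       las = 2, tick = FALSE)
  graphics::legend("topright", legend = .NT, fill = pal, bty = "n")
  invisible(list(type = "dual_strand_barplot", variant = variant_id,
                 samples = ds$samples, plus = up, minus = dn,
                 p_plus = p_up, p_minus = p_dn,
                 labels_plus = lab_up, labels_minus = lab_dn))
}

#' Read a gene annotation for plotting
#'
#' GTF files keep `gene` and `exon` features (exons are collapsed per
#' gene for drawing); BED files are used as-is, one feature per record.
#'
#' @param path GTF or BED file.
#' @return `data.frame` with `chrom, start, end, name, feature`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  meta <- S4Vectors::mcols(gr)
  if ("type" %in% names(meta)) {             # GTF/GFF
    df$feature <- as.character(meta$type)
    df$name <- if ("gene_id" %in% names(meta))
      as.character(meta$gene_id) else NA_character_
    df <- df[df$feature %in% c("gene", "exon"), , drop = FALSE]
  } else {                                    # BED
    df$feature <- "region"
    df$name <- if ("name" %in% names(meta)) as.character(meta$name)
               else paste0("feature", seq_len(nrow(df)))
  }
  df
}

#' Region view: per-SNP mini-barplots along genomic coordinates
#'
#' Draws one mini-barplot (counts or reference fractions, one bar per
#' sample) for every variant inside `region`, evenly laid out in panel
#' space, each connected by a guide line to its genomic coordinate on a
#' horizontal axis. An optional gene/exon track from a GTF or BED file is
#' drawn beneath. Useful to judge the consistency of allelic imbalance
#' across the heterozygous SNPs of one gene.
#'
#' @param ds an `ase_dataset`.
#' @param region `"chrom:start-end"` (1-based closed).
#' @param annotation optional GTF/BED path or the `data.frame` from
#'   [read_annotation()].
#' @param mode `"count"` (total ref+alt depth split per allele) or
#'   `"fraction"`.
#' @param out output image path.
#' @param expected fraction-mode guide line (default 0.5).
#' @param min_depth depth gate for fraction mode.
#' @return invisibly, a layout list; `panels` holds one row per drawn
#'   variant with its genomic `pos` and panel `x_center` (monotone in
#'   `pos`).
#' @export
locationplot <- function(ds, region, annotation = NULL,
                         mode = c("count", "fraction"), out,
                         expected = 0.5, min_depth = 1L) {
  stopifnot(inherits(ds, "ase_dataset"))
  mode <- match.arg(mode)
  r <- .parse_region(region)
  sub <- subset_dataset(ds, region = r)
  if (n_variants(sub) == 0L) {
    same_chrom <- ds$variants[ds$variants$chrom == r$chrom, , drop = FALSE]
    nearest <- if (nrow(same_chrom)) {
      d <- pmin(abs(same_chrom$pos - r$start), abs(same_chrom$pos - r$end))
      paste(head(same_chrom$id[order(d)], 3L), collapse = ", ")
    } else "none on that chromosome"
    stop("no variants in region ", r$chrom, ":", r$start, "-", r$end,
         "; nearest: ", nearest)
  }
  sub <- resolve_alleles(sub)
  nv <- n_variants(sub)
  ns <- n_samples(sub)
  pal <- .nt_palette()

  panel_w <- 1 / nv
  x_center <- (seq_len(nv) - 0.5) * panel_w
  gx <- (sub$variants$pos - r$start) / max(1L, r$end - r$start)

  .open_device(out, width = max(7, 1.6 * nv), height = 5.5)
  on.exit(dev.off())
  par(mar = c(4, 4, 3, 1))
  plot(NA, xlim = c(0, 1), ylim = c(-0.55, 1.05), xlab = "", ylab = "",
       xaxt = "n", yaxt = "n", bty = "n",
       main = paste0(r$chrom, ":", r$start, "-", r$end))
  axis(2, at = c(0, 0.5, 1), labels = c("0", "0.5", "1"))

  frac <- allele_fractions(sub, min_depth = min_depth)
  for (v in seq_len(nv)) {
    x0 <- (v - 1) * panel_w + 0.12 * panel_w
    x1 <- v * panel_w - 0.12 * panel_w
    bw <- (x1 - x0) / ns
    if (mode == "fraction") {
      for (i in seq_len(ns)) {
        f <- frac[i, v]
        rect(x0 + (i - 1) * bw, 0, x0 + i * bw,
             ifelse(is.na(f), 0, f), col = "grey40", border = "white")
      }
      segments(x0, expected, x1, expected, lwd = 2)
    } else {
      k <- .allele_count_matrix(sub, "ref", "both")[, v]
      a <- .allele_count_matrix(sub, "alt", "both")[, v]
      tot <- max(1L, max(k + a))
      for (i in seq_len(ns)) {
        rect(x0 + (i - 1) * bw, 0, x0 + i * bw, k[i] / tot,
             col = pal[sub$variants$ref[v]], border = "white")
        rect(x0 + (i - 1) * bw, k[i] / tot, x0 + i * bw, (k[i] + a[i]) / tot,
             col = pal[sub$variants$alt[v]], border = "white")
      }
    }
    text((x0 + x1) / 2, 1.03, sub$variants$id[v], cex = 0.7)
    # guide line from panel to genomic coordinate
    segments(x_center[v], -0.02, gx[v], -0.25, col = "grey50")
    segments(gx[v], -0.25, gx[v], -0.3, col = "grey30")
  }
  # genomic axis
  segments(0, -0.3, 1, -0.3)
  text(c(0, 1), -0.36, c(r$start, r$end), cex = 0.7)

  ann <- NULL
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) read_annotation(annotation)
           else annotation
    ann <- ann[ann$chrom == r$chrom & ann$end >= r$start &
                 ann$start <= r$end, , drop = FALSE]
    for (g in unique(ann$name)) {
      rows <- ann[ann$name == g, , drop = FALSE]
      gx0 <- max(0, (min(rows$start) - r$start) / max(1L, r$end - r$start))
      gx1 <- min(1, (max(rows$end) - r$start) / max(1L, r$end - r$start))
      rect(gx0, -0.48, gx1, -0.42, col = "khaki", border = "grey30")
      ex <- rows[rows$feature == "exon", , drop = FALSE]
      for (e in seq_len(nrow(ex)))
        rect(max(0, (ex$start[e] - r$start) / max(1L, r$end - r$start)),
             -0.5, min(1, (ex$end[e] - r$start) / max(1L, r$end - r$start)),
             -0.4, col = "goldenrod", border = NA)
      text((gx0 + gx1) / 2, -0.54, g, cex = 0.7)
    }
  }
  invisible(list(
    type = "locationplot", mode = mode, region = r,
    samples = sub$samples,
    panels = data.frame(id = sub$variants$id, pos = sub$variants$pos,
                        x_center = x_center, genomic_x = gx,
                        stringsAsFactors = FALSE),
    n_panels = nv,
    annotation = ann
  ))
}
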