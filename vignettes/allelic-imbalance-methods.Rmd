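---
title: "Counting and testing allele-specific expression with asekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and testing allele-specific expression with asekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asekit)
```

## The problem

At a heterozygous SNP, RNA-seq reads can be assigned to the allele they were
transcribed from. If a regulatory variant makes one haplotype transcribe more
than the other, the read ratio at every heterozygous SNP of that gene departs
from 1:1 — allelic imbalance (AI). Detecting it needs only one informative
individual, but the measurement sits on top of several technical steps
(library preparation, alignment, filtering) that each can bias the allele
counts. asekit implements the desk-side part of that workflow: filtered
allele counting from aligned reads, a strand-aware count container, exact
per-cell imbalance tests with adjustable expected ratios, reference
N-masking against mapping bias, region-level visualization, and a simulator
that provides ground truth for all of it.

## The count container

The central object is a four-axis integer tensor

```
counts[sample, variant, nucleotide (A,C,G,T), strand (plus, minus, both)]
```

plus the variant table, sample ids, the library strandedness, and optional
phenotypes and genotypes. Two structural invariants are enforced at
construction and preserved by every operation:

* stranded data: `both = plus + minus`, element-wise (the `both` slice is
  recomputed, never trusted);
* unstranded data: all counts live on `both`; `plus`/`minus` are zero.

Only the four standard nucleotides are tracked. A read showing `N`, an
insertion or deletion, or a reference skip at the SNP base is not an allele
observation and contributes nothing; indel and multi-nucleotide variants are
out of scope throughout. Coordinates are 1-based and intervals fully closed
everywhere a user sees them, matching VCF and GTF conventions.

Fractions, genotypes and MAF are all derived from the tensor:

* `allele_fractions()` returns `ref / (ref + alt)`; the two non-(ref, alt)
  nucleotides are ignored, and a cell under the depth gate is an explicit
  `NA` — never 0, 1, or a p-value of 1.
* `infer_genotypes()` calls a cell heterozygous when depth ≥ 10 and the
  minor-of-(ref, alt) fraction is ≥ 0.10, homozygous for the major allele
  below that band, and no-call under the depth gate. These defaults are
  deliberately permissive: at depth 30 a truly balanced het cell is called
  het with probability above 0.999 (binomial tail), while contamination at a
  homozygous site rarely reaches 10%. Genotypes provided from a VCF always
  override inference — inference exists for datasets that arrive without
  calls.
* `maf()` computes the minor-allele frequency across samples from diploid
  calls, `MAF = min(f, 1 - f)` with `f = (2·hom_ref + het) / (2·called)`;
  no-calls leave the denominator. MAF could alternatively be pooled from raw
  allele counts; the genotype-based definition was chosen because it matches
  how the quantity is used (selecting SNPs informative in enough
  individuals) and is robust to depth imbalance between samples. A
  `maf_filter(ds, 0.1)` keeps variants with MAF strictly above the
  threshold, the conventional cutoff for "informative" SNPs.
* `top_alleles()` resolves missing ref/alt metadata by ranking nucleotides
  on total count; ties break alphabetically so that the result is
  deterministic, which matters more here than any biological prior.

## Counting semantics

`count_alleles()` performs a single-base pileup at each variant from one
indexed BAM per sample. The admission rules (a `count_filter`) are, in
order: mapped; not secondary/supplementary; not a duplicate; properly
paired (paired reads only); mapping quality ≥ 20; base quality at the SNP
base ≥ 10. All thresholds are inclusive and all rules can be relaxed; the
defaults follow common allele-specific-expression practice, since no single
standard exists. Each rejection is tallied by reason in a per-sample
counting report.

Two semantic decisions deserve spelling out:

* **A fragment is one observation.** When both mates of a pair cover the
  SNP, the fragment contributes once: among the reads that could contribute
  (admitted, with an aligned A/C/G/T base at the position), the
  first-encountered mate of each query name wins. A mate that cannot
  contribute does not block its partner. This keeps doubled mate overlap
  from doubling the evidence.
* **The base at the SNP comes from the CIGAR.** Soft-clipped bases never
  align to reference positions; deletions and reference skips spanning the
  position yield no base.

Strandedness is declared by the user, never auto-detected. For the dUTP
(`fr-firststrand`) protocol the second-in-pair read has the transcript's
orientation, so a forward-mapped read2 (or reverse-mapped read1) means a
plus-strand transcript; `fr-secondstrand` is the inverse; single-end reads
are treated as read1. Misdeclaring the protocol silently swaps the strands —
the package documents this rather than guessing.

The counting path is validated two independent ways: against a brute-force
per-read oracle (own CIGAR walker, own flag arithmetic) on randomized
synthetic BAMs, and against the simulator's truth tables (below), which it
must reproduce exactly when no sequencing errors are injected.

## Testing for imbalance

For a cell with `k` reference reads out of `n = ref + alt` informative
reads, two tests of the null `k ~ Binomial(n, p0)` are provided, where `p0`
is the expected reference fraction (default 0.5):

* **Exact binomial** (`binom_test_matrix`): the two-sided p-value is the
  minimum-likelihood sum `Σ P(X = i)` over all `i` with
  `P(X = i) ≤ P(X = k)`, with a 1e-7 relative tolerance for ties. This is
  the de-facto standard definition of the two-sided exact test; sidedness
  had to be pinned down somewhere, and this choice makes the test
  reproducible against any standard implementation.
* **Chi-square** (`chisq_test_matrix`): the 1-df goodness-of-fit statistic
  `X² = (k − n·p0)²/(n·p0) + ((n−k) − n(1−p0))²/(n(1−p0))`, upper-tail
  p-value, no continuity correction. The exact test covers small `n`, so
  the correction buys little, and the uncorrected statistic has a clean
  closed form that an independent oracle can check.

Cells are tested only when `n ≥ min_depth` (default 10) and — by default —
only when heterozygous, since imbalance is undefined for homozygotes;
everything else is `NA`. Counts on the two other nucleotides are excluded
from `n` and reported as `other_counts`, a per-cell sequencing-error
diagnostic. `adjust_pvalues()` applies Benjamini–Hochberg or Bonferroni
jointly over all non-missing cells.

Because the exact test is discrete, its realized size at `α = 0.05` is
conservative: about 0.033 at depth 50 under a balanced null, with the
chi-square near 0.065. Power at depth 50 against a true fraction of 0.7 is
about 0.78. The test suite re-measures these rates on 2000 simulated cells.

### Mapping bias and the expected ratio

Reads carrying the alternative allele mismatch the reference and map
slightly less often, inflating the reference fraction above 0.5 even
without any true imbalance. Two countermeasures are implemented:

* `set_expected_from_counts()` estimates per-variant expected fractions
  from null material with known 1:1 truth — simulated reads equally
  distributed over both alleles, or DNA sequencing — as the pooled
  `ref/(ref+alt)` across samples, clamped to [0.05, 0.95] (an estimate of
  exactly 0 or 1 says the variant is unusable, not that the null is
  degenerate), falling back to 0.5 under a pooled-depth gate. Feeding the
  result into the tests recenters the null.
* `mask_reference()` writes a copy of the reference FASTA with every known
  SNV position replaced by `N`, for realignment. Masking touches nothing
  else: line wrapping, headers and the case of unmasked bases are preserved
  byte-for-byte, soft-masked bases at variant positions become uppercase
  `N` (aligners treat `N` uniformly), multi-allelic records mask their
  position once, and indels are skipped and counted. `verify_masking()`
  independently proves that the differing-position set equals the in-bounds
  SNV set.

The calibration loop is validated end to end: reads simulated with an
alt-allele loss of 1/3 realize a null fraction near 0.6; testing those
cells against 0.5 rejects most of them, while testing against ratios
estimated from a disjoint null simulation restores the rejection rate to
the nominal few percent. The suite runs this at depth 200 with 60 SNPs ×
4 test samples and an 8-sample calibration run — depth 200 because the
exact test only reaches useful power against a 0.6-vs-0.5 shift above
roughly 150 informative reads, and a deeper pooled calibration keeps the
estimated ratios from re-introducing noise.

## The simulator

`simulate_ase()` emits a complete toy experiment — reference FASTA, VCF 4.2
with per-sample genotypes, one coordinate-sorted indexed BAM per sample,
and a truth TSV of realized per-cell allele counts — from a single seeded
configuration. The generative model:

* reference drawn uniformly over A/C/G/T; SNVs placed at least one read
  length from chromosome ends and more than one fragment length apart, so
  no fragment can overlap two SNPs (required for the exact recount
  property);
* per sample × SNP cell, exactly `depth` fragments; het cells draw their
  reference-fragment count from `Binomial(depth, fraction)`, homozygotes
  emit one allele; alt fragments are then dropped with probability
  `ref_bias`, an abstract stand-in for alignment loss;
* each fragment becomes one FR read pair fully covering the fragment
  (`read_length ≤ fragment_length ≤ 2·read_length`, so mates overlap in the
  middle and exercise the once-per-fragment rule), perfect-match CIGAR,
  MAPQ 60, base quality 40; `error_rate` injects uniform substitutions to
  exercise the other-nucleotide diagnostic;
* first/second-in-pair assignment follows the declared protocol and each
  SNP's transcript strand, so stranded counting can be checked against
  truth per strand.

Defaults (1 chromosome of 10 kb, 10 SNPs, 2 samples, depth 50, 75 bp reads,
120 bp fragments) are sized for fast, fully-checkable unit fixtures; the
validation suite scales single dimensions up where a property needs it
(500 SNPs at depth 100 for fraction recovery; depth 10⁴ for the thinning
ratio; 2000 cells for size/power).

What the simulator does **not** emulate bounds what passing tests show
about real data: no splicing or introns, no indels, no base-quality
profiles, no fragment-length variation, no correlated errors, and mapping
bias is a Bernoulli thinning rather than an aligner artifact. The
statistical machinery is therefore validated exactly, but conclusions
about a real aligner's bias still require the masking/realignment route.

## Numerical and interface choices

* Missing is missing: under-depth fractions and p-values are `NA`
  throughout, so downstream summaries cannot mistake "no data" for
  "balanced".
* `binom_pvalue` ties use a 1e-7 relative tolerance, mirroring standard
  practice, so symmetric cases include both tails exactly.
* Serialization is a wide TSV (variants × per-sample count columns
  `sample.nt.strand`) with `#` header lines for strandedness and
  phenotypes; it round-trips losslessly and diffs cleanly under version
  control.
* Plots are written to files (`.svg` recommended: output is
  byte-deterministic for identical input, which the tests exploit); every
  plot function also returns its layout — panel positions, bar heights,
  annotation labels — so structure is testable without pixel comparison.
  The p-value annotation convention is three fixed decimals down to 0.001
  and scientific notation below.
* The CLI (`inst/cli/asekit.R`) wires the same functions into `count`,
  `test`, `mask`, `plot`, `simulate` and `report` subcommands with
  config-file defaults and exit codes 0/2/1
  (success/validation/runtime).

## Known limitations

No haplotype phasing, no aggregation across SNPs of a gene, no
beta-binomial overdispersion model (cells are tested independently; true
biological replicates of the same individual will look anticonservative if
treated as independent), no QTL association layer, and no aligner is run —
reference masking produces the FASTA but realignment happens outside the
package.
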