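# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: the counting oracle re-walks CIGARs with its own
# parser and re-derives the protocol strand from raw flag arithmetic; the
# binomial oracle builds the mass function from log-binomial coefficients.

oracle_cigar_base <- function(pos, read_start, cigar, seq) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]", "", ops))
  typ <- sub("[0-9]+", "", ops)
  rpos <- read_start
  qpos <- 1L
  for (i in seq_along(typ)) {
    t <- typ[i]; L <- lens[i]
    ref_c <- t %in% c("M", "=", "X", "D", "N")
    qry_c <- t %in% c("M", "=", "X", "I", "S")
    if (ref_c && pos >= rpos && pos <= rpos + L - 1L) {
      if (t %in% c("M", "=", "X"))
        return(list(base = substring(seq, qpos + pos - rpos, qpos + pos - rpos),
                    qoff = qpos + pos - rpos))
      return(NULL)  # deletion / skip spans the position
    }
    if (ref_c) rpos <- rpos + L
    if (qry_c) qpos <- qpos + L
  }
  NULL
}

oracle_strand <- function(flag, strandedness) {
  if (strandedness == "unstranded") return("both")
  is_r2 <- (flag %/% 128L) %% 2L == 1L
  rev <- (flag %/% 16L) %% 2L == 1L
  plus <- xor(is_r2, rev)
  if (strandedness == "fr-secondstrand") plus <- !plus
  if (plus) "plus" else "minus"
}

# brute-force per-read tally over one BAM; returns variants x 4 x 3 array
oracle_count_bam <- function(bam, variants, filter = count_filter(),
                             strandedness = "unstranded") {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  nt <- c("A", "C", "G", "T")
  st <- c("plus", "minus", "both")
  out <- array(0L, c(nrow(variants), 4L, 3L),
               dimnames = list(variants$id, nt, st))
  seen <- lapply(seq_len(nrow(variants)), function(i) character(0))
  for (r in seq_along(rec$flag)) {
    flag <- rec$flag[r]
    if ((flag %/% 4L) %% 2L == 1L) next           # unmapped
    chrom <- as.character(rec$rname[r])
    seq <- as.character(rec$seq[r])
    for (j in which(variants$chrom == chrom)) {
      pos <- variants$pos[j]
      if (pos < rec$pos[r]) next
      hit <- oracle_cigar_base(pos, rec$pos[r], rec$cigar[r], seq)
      if (is.null(hit) || !hit$base %in% nt) next
      bq <- utf8ToInt(substring(as.character(rec$qual[r]),
                                hit$qoff, hit$qoff)) - 33L
      adm <- admit_read(list(flag = flag, mapq = rec$mapq[r], baseq = bq),
                        filter)
      if (!adm$admitted) next
      if (rec$qname[r] %in% seen[[j]]) next       # fragment already counted
      seen[[j]] <- c(seen[[j]], rec$qname[r])
      s <- oracle_strand(flag, strandedness)
      out[j, hit$base, s] <- out[j, hit$base, s] + 1L
    }
  }
  if (strandedness != "unstranded")
    out[, , "both"] <- out[, , "plus"] + out[, , "minus"]
  out
}

# two-sided minimum-likelihood binomial p-value from first principles
oracle_binom_pval <- function(k, n, p0) {
  i <- 0:n
  logp <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
  pmf <- exp(logp)
  min(1, sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)]))
}
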