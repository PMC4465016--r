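# fixture builders used across test files

# empty samples x variants x 4 x 3 tensor
zero_tensor <- function(ns, nv) array(0L, c(ns, nv, 4L, 3L))

nt_index <- function(nt) match(nt, c("A", "C", "G", "T"))

# dataset from ref/alt count matrices (samples x variants), unstranded,
# every variant ref/alt as given
ds_from_ref_alt <- function(k, a, ref = "A", alt = "G",
                            chrom = "chr1", genotypes = NULL) {
  k <- as.matrix(k); a <- as.matrix(a)
  ns <- nrow(k); nv <- ncol(k)
  ref <- rep_len(ref, nv); alt <- rep_len(alt, nv)
  v <- snp_variants(chrom, seq_len(nv) * 100L, ref = ref, alt = alt)
  cnt <- zero_tensor(ns, nv)
  for (j in seq_len(nv)) {
    cnt[, j, nt_index(ref[j]), 3L] <- k[, j]
    cnt[, j, nt_index(alt[j]), 3L] <- a[, j]
  }
  build_dataset(cnt, v, paste0("s", seq_len(ns)), "unstranded",
                genotypes = genotypes)
}

# write a SAM fixture and return an indexed BAM path.
# reads: data.frame(qname, flag, rname, pos, mapq, cigar, seq, qual_char)
# qual_char is a single Phred+33 character repeated over the read.
sam_fixture <- function(reads, chrom_lengths = c(chr1 = 1000L),
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chrom_lengths), "\tLN:", chrom_lengths))
  body <- character(0)
  if (nrow(reads)) {
    if (is.null(reads$rnext)) reads$rnext <- "*"
    if (is.null(reads$pnext)) reads$pnext <- 0L
    if (is.null(reads$tlen)) reads$tlen <- 0L
    qual <- vapply(seq_len(nrow(reads)),
                   function(i) strrep(reads$qual_char[i], nchar(reads$seq[i])),
                   character(1))
    body <- paste(reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$rnext, reads$pnext,
                  reads$tlen, reads$seq, qual, sep = "\t")
  }
  sam <- file.path(dir, paste0("fix", as.integer(stats::runif(1, 1, 1e6)),
                               ".sam"))
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                   indexDestination = TRUE)
}

# a simple aligned read row; flag 0 = single-end forward primary
read_row <- function(qname, pos, seq, flag = 0L, mapq = 60L,
                     cigar = paste0(nchar(seq), "M"), rname = "chr1",
                     qual_char = "I") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual_char = qual_char,
             stringsAsFactors = FALSE)
}
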