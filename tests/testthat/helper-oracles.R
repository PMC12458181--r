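# Independent brute-force oracles shared across test files. These stay
# deliberately naive (per-position loops, direct genetic-code lookup) so
# they cannot share a defect with the implementation paths they check.

GENCODE <- Biostrings::GENETIC_CODE

# Naive motif scan over one region.
brute_occurrences <- function(rec, motif, kind, frame, utrmode) {
  region <- switch(as.character(utrmode), "0" = rec$utr5, "1" = rec$cds,
                   "2" = rec$utr3)
  s0 <- region[1] - 1L; e0 <- region[2] - 1L
  if (e0 < s0) return(integer(0))
  cs <- rec$cds[1] - 1L
  hits <- integer(0)
  if (kind == 0) {
    L <- nchar(motif)
    for (p in s0:(e0 - L + 1L)) {
      if (p + L - 1L > e0) next
      if (substr(rec$sequence, p + 1L, p + L) != motif) next
      if (frame %in% 0:2 && (p - cs) %% 3L != frame) next
      hits <- c(hits, p)
    }
  } else {
    naa <- nchar(motif)
    for (p in s0:e0) {
      if ((p - (cs + frame)) %% 3L != 0L) next
      if (p + 3L * naa - 1L > e0) next
      pep <- paste(vapply(0:(naa - 1L), function(j)
        unname(GENCODE[substr(rec$sequence, p + 3L * j + 1L,
                              p + 3L * j + 3L)]), ""), collapse = "")
      if (pep == motif) hits <- c(hits, p)
    }
  }
  hits
}

# Naive all-transcript substring occurrence count for one read.
brute_site_count <- function(txome, read) {
  k <- nchar(read)
  total <- 0L
  for (rec in txome$records) {
    n <- rec$length - k + 1L
    if (n < 1L) next
    win <- substring(rec$sequence, 1:n, k:(k + n - 1L))
    total <- total + sum(win == read)
  }
  total
}

# Genes sharing a verbatim 30-nt segment in otherwise distinct sequence.
dup_txome <- function(threeway = FALSE) {
  seg <- "ACGTGTCAAGTTGACCATGCGATCAGGTCA"                # 30 nt, aperiodic
  mk <- function(gene, utr5, codons, prefix, suffix) {
    toy_record(gene, utr5 = utr5, cds_codons = codons,
               utr3 = paste0(prefix, seg, suffix))
  }
  recs <- list(
    mk("D1", "AGTCAGTCAGTC", c("GTT", "CAC", "TGG", "ATC", "GAA", "CTT"),
       "TTTTT", "CCCCC"),
    mk("D2", "GACCTGACCTGA", c("CAA", "GGT", "ACT", "TCG", "ATT", "GCC"),
       "GGGGG", "AAAAA"))
  recs[[3]] <- toy_record("D3", utr5 = "CCATTCCGATCG",
                          cds_codons = c("TGG", "GAT", "CGC", "TAC", "AAC",
                                         "GGA"),
                          utr3 = "CTGATCCGTAACGGTTACCA")
  if (threeway)
    recs[[4]] <- mk("D4", "TGGCCATTGGAC",
                    c("TAC", "CGA", "TTG", "CAT", "GTA", "AGC"),
                    "CATCA", "TGATG")
  toy_transcriptome(recs)
}
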