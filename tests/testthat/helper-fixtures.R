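# Fixtures built in code: tiny hand-assembled transcriptomes and SAM
# writers independent of the package's own simulator, so ingest tests have
# an external reference for flag arithmetic and coordinates.

toy_header <- function(gene = "G1", alias = "TOY", u5 = 15L, cds = 30L,
                       u3 = 15L) {
  len <- u5 + cds + u3
  sprintf("%s|T_%s|P_%s|NM_1|NP_1|%s|%d|UTR5:1-%d|CDS:%d-%d|UTR3:%d-%d",
          gene, gene, gene, alias, len, u5, u5 + 1L, u5 + cds,
          u5 + cds + 1L, len)
}

# One record with a fully specified sequence (CDS = ATG + codons + stop).
toy_record <- function(gene = "G1", alias = "TOY", utr5 = "AAACCCGGGTTTAAA",
                       cds_codons = c("GCC", "CCA"),
                       cds = NULL, utr3 = "TTTGGGCCCAAATTT") {
  if (is.null(cds)) cds <- paste0("ATG", paste(cds_codons, collapse = ""), "TAA")
  rec <- parse_header(toy_header(gene, alias, nchar(utr5), nchar(cds),
                                 nchar(utr3)))
  rec$sequence <- paste0(utr5, cds, utr3)
  rec
}

toy_transcriptome <- function(recs) {
  riboscope:::new_transcriptome(recs, "test fixture")
}

# Deterministic 3-gene fixture with known sequences.
tiny_txome <- function() {
  r1 <- toy_record("G1", "ALPHA", utr5 = "AAATGGCCTAAGGAA",
                   cds_codons = c("CCA", "AGC", "AAA", "GGG"))
  r2 <- toy_record("G2", "BETA", utr5 = strrep("C", 12),
                   cds_codons = c("CCA", "CCA", "GGA", "TGC"),
                   utr3 = paste0("GG", "ATGGCATGA", "CCCC"))
  r3 <- toy_record("G3", "GAMMA", utr5 = strrep("AC", 10),
                   cds_codons = c("TTT", "CCG", "CCG", "GGA", "AAA"),
                   utr3 = strrep("T", 18))
  toy_transcriptome(list(r1, r2, r3))
}

# Write a SAM by hand. reads: data.frame(qname, flag, gene, pos1, len).
# Unmapped rows (flag & 4) get RNAME "*".
write_sam_fixture <- function(txome, reads, path = tempfile(fileext = ".sam")) {
  lens <- vapply(txome$records, `[[`, 0L, "length")
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    unmapped <- bitwAnd(r$flag, 4L) != 0L
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                              r$qname, r$flag,
                              if (unmapped) "*" else r$gene,
                              if (unmapped) 0L else r$pos1,
                              if (unmapped) "*" else sprintf("%dM", r$len),
                              strrep("A", max(r$len, 1L))))
  }
  writeLines(lines, path)
  path
}

simple_reads <- function(gene, pos1, len, flag = 0L) {
  data.frame(qname = sprintf("r%d", seq_along(pos1)), flag = flag,
             gene = gene, pos1 = pos1, len = len,
             stringsAsFactors = FALSE)
}

# Build a rocc_store directly from per-gene raw tracks (bypasses SAM IO)
# for analysis-level tests that need exact occupancy values.
manual_rocc <- function(txome, tracks, endmode = "5prime", units = "rpm",
                        denominator = 1e6) {
  stopifnot(all(names(tracks) %in% names(txome$records)))
  full <- lapply(txome$records, function(r) numeric(r$length))
  for (g in names(tracks)) {
    stopifnot(length(tracks[[g]]) == txome$records[[g]]$length)
    full[[g]] <- as.numeric(tracks[[g]])
  }
  structure(list(tracks = full, records = txome$records, endmode = endmode,
                 smallsize = 1L, largesize = 100L, normalize = -1,
                 denominator = denominator,
                 total_mapped = denominator, reads_in_window = NA_integer_,
                 tallies = c(total = NA_integer_), units = units,
                 source_sam = "manual"),
            class = "rocc_store")
}
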