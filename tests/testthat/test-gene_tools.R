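# Track shifting, per-gene position tables, region/frame counting, smORFs.

test_that("apply_shift moves values by the stated offset and tallies losses", {
  v <- c(1, 0, 2, 0, 0, 5)
  s0 <- apply_shift(v, 0)
  expect_equal(as.numeric(s0), v)
  expect_equal(attr(s0, "dropped"), 0)
  s2 <- apply_shift(v, 2)
  expect_equal(as.numeric(s2), c(0, 0, 1, 0, 2, 0))
  expect_equal(attr(s2, "dropped"), 5)        # values at the tail fall off
  s1 <- apply_shift(c(0, 0, 1), 1)
  expect_equal(attr(s1, "dropped"), 1)        # last position + 1 -> gone
  sm <- apply_shift(v, -2)
  expect_equal(as.numeric(sm), c(2, 0, 0, 5, 0, 0))
  expect_equal(attr(sm, "dropped"), 1)
  # a 12-position example: track[0] (0-based) lands on track[12]
  w <- numeric(20); w[1] <- 7
  expect_equal(as.numeric(apply_shift(w, 12))[13], 7)
})

test_that("writegene2 reports per-position occupancy for one or more stores", {
  tx <- tiny_txome()
  g1len <- tx$records$G1$length
  tr <- numeric(g1len); tr[5] <- 3.5           # one read's 5' end at row 5
  rocc <- manual_rocc(tx, list(G1 = tr))
  tab <- writegene2(rocc, "G1")
  expect_equal(nrow(tab), g1len)
  expect_equal(tab$rocc[5], 3.5)
  expect_equal(sum(tab$rocc != 0), 1L)
  expect_equal(tab$position, seq_len(g1len))

  # column sum equals the genelist region total for shift 0
  gl <- genelist(rocc, shift = 0)
  expect_equal(sum(tab$rocc),
               with(gl[gl$gene_id == "G1", ],
                    utr5_raw + cds_raw + utr3_raw) * 1e6 / rocc$denominator)

  # alias lookup and multiple stores
  rocc2 <- manual_rocc(tx, list(G1 = tr * 2))
  tab2 <- writegene2(list(a = rocc, b = rocc2), c("ALPHA", "G2"))
  expect_equal(ncol(tab2), 4L)
  expect_equal(nrow(tab2), g1len + tx$records$G2$length)
  expect_equal(tab2$b[5], 7)
  expect_error(writegene2(rocc, "NOPE"), "NOPE")
})

test_that("genelist sums regions, computes RPKM, and splits CDS frames", {
  tx <- tiny_txome()
  rec <- tx$records$G1
  cs1 <- rec$cds[1]                            # 1-based CDS start
  tr <- numeric(rec$length); tr[cs1] <- 4      # all occupancy on cds start
  rocc <- manual_rocc(tx, list(G1 = tr))
  gl <- genelist(rocc, shift = 0, doextra = 1)
  g1 <- gl[gl$gene_id == "G1", ]
  expect_equal(g1$cds_raw, 4)
  expect_equal(g1$utr5_raw + g1$utr3_raw, 0)
  expect_equal(c(g1$frame0, g1$frame1, g1$frame2), c(4, 0, 0))

  # 5'-assigned reads 12 nt upstream of cds start count in CDS frame 0 after shift 12
  tr2 <- numeric(rec$length); tr2[cs1 - 12] <- 2
  gl2 <- genelist(manual_rocc(tx, list(G1 = tr2)), shift = 12, doextra = 1)
  g2 <- gl2[gl2$gene_id == "G1", ]
  expect_equal(g2$cds_raw, 2)
  expect_equal(g2$frame0, 2)

  # frame counts always sum to the CDS count
  set.seed(42)
  tr3 <- stats::rpois(rec$length, 2)
  gl3 <- genelist(manual_rocc(tx, list(G1 = tr3)), shift = 5, doextra = 1)
  g3 <- gl3[gl3$gene_id == "G1", ]
  expect_equal(g3$frame0 + g3$frame1 + g3$frame2, g3$cds_raw)
  # adding 3 to the shift leaves every position's frame unchanged
  gl3b <- genelist(manual_rocc(tx, list(G1 = tr3)), shift = 8, doextra = 1)
  sh <- apply_shift(tr3, 8)
  expect_equal(gl3b$frame0[gl3b$gene_id == "G1"],
               sum(sh[seq(rec$cds[1], rec$cds[2], by = 3)]))

  # region sums plus the shift-dropped tally equal the track total
  expect_equal(g3$utr5_raw + g3$cds_raw + g3$utr3_raw + g3$shift_dropped,
               sum(tr3))
})

test_that("RPKM normalizes by region length in kilobases", {
  # 2 rpm in a 100-nt 5'UTR -> RPKM 20
  rec <- parse_header(">GL|T|P|N|NP|AL|400|UTR5:1-100|CDS:101-250|UTR3:251-400")
  rec$sequence <- paste0(strrep("A", 100), "ATG", strrep("GCA", 48), "TAA",
                         strrep("T", 150))
  tx <- toy_transcriptome(list(rec))
  tr <- numeric(400); tr[c(10, 20)] <- 1       # 2 rpm total in the UTR
  gl <- genelist(manual_rocc(tx, list(GL = tr)), shift = 0)
  expect_equal(gl$utr5_rpkm, 20)
  expect_equal(gl$cds_rpkm, 0)
})

test_that("find_smorfs locates ORFs and applies start/stop and length rules", {
  # 5'UTR "AAATGGCCTAAGGAA": ATG at offset 2, ORF ATG-GCC-TAA -> 2 aa
  tx <- tiny_txome()
  orfs <- find_smorfs(tx$records$G1, utr_side = 5)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start_pos, 2L)
  expect_equal(orfs$stop_pos, 8L)
  expect_equal(orfs$aa_length, 2L)
  expect_equal(orfs$start_codon, "ATG")
  expect_true((orfs$stop_pos - orfs$start_pos) %% 3 == 0)

  # near-cognate starts: results must match a brute-force Hamming scan
  rec <- tx$records$G3                          # utr5 "ACACACACACACACACACAC"
  near <- find_smorfs(rec, utr_side = 5, mismatches = 1)
  brute_starts <- function(seq, u5) {
    hits <- integer(0)
    for (p in 0:(u5 - 3)) {
      cod <- substr(seq, p + 1, p + 3)
      d <- sum(strsplit(cod, "")[[1]] != c("A", "T", "G"))
      if (d <= 1) hits <- c(hits, p)
    }
    hits
  }
  cand <- brute_starts(rec$sequence, riboscope:::span_len(rec$utr5))
  expect_true(all(near$start_pos %in% cand))
  # mismatches = 0 results are a subset of mismatches = 1 results
  strict <- find_smorfs(rec, utr_side = 5, mismatches = 0)
  expect_true(all(strict$stop_pos %in% near$stop_pos))

  # two in-frame ATGs sharing a stop: smallest = 1 keeps the downstream one
  r2 <- toy_record("GD", utr5 = paste0("T", "ATG", "ATG", "CCC", "TAA", "TT"),
                   cds_codons = "AAA")
  sm1 <- find_smorfs(r2, 5, smallest = 1)
  sm0 <- find_smorfs(r2, 5, smallest = 0)
  same_stop <- intersect(sm1$stop_pos, sm0$stop_pos)
  expect_true(length(same_stop) >= 1)
  s <- same_stop[1]
  expect_gt(sm1$start_pos[sm1$stop_pos == s], sm0$start_pos[sm0$stop_pos == s])

  # lengththresh: k > 0 strictly longer; k < 0 exact length
  r3 <- toy_record("GE", utr5 = paste0("AA", "ATG", strrep("GCT", 4), "TGA", "A"),
                   cds_codons = "AAA")
  expect_equal(nrow(find_smorfs(r3, 5, lengththresh = 4)), 1L)  # 5 aa > 4
  expect_equal(nrow(find_smorfs(r3, 5, lengththresh = 5)), 0L)  # not > 5
  expect_equal(find_smorfs(r3, 5, lengththresh = -5)$aa_length, 5L)
  expect_equal(nrow(find_smorfs(r3, 5, lengththresh = -4)), 0L)
})

test_that("dORF search extends past the 3'UTR only to the transcript end", {
  # G2's 3'UTR "GGATGGCATGACCCC": ATG at utr3 offset 2, stop TGA in range
  tx <- tiny_txome()
  rec <- tx$records$G2
  d <- find_smorfs(rec, utr_side = 3)
  expect_true(nrow(d) >= 1)
  u3start0 <- rec$utr3[1] - 1L
  expect_true(all(d$start_pos >= u3start0))
  expect_equal(d$utr_side, rep(3L, nrow(d)))
  # re-extracted start codons match the sequence
  expect_true(all(substring(rec$sequence, d$start_pos + 1, d$start_pos + 3)
                  == d$start_codon))
})

test_that("smorflist counts in-frame occupancy including the stop position", {
  # uniform 1 rpm/nt across an ORF of 5 codons + stop -> 6 in-frame reads
  r <- toy_record("GS", utr5 = paste0("CC", "ATG", strrep("GCT", 4), "TGA",
                                      strrep("C", 7)),
                  cds_codons = c("AAA", "CCC"))
  tx <- toy_transcriptome(list(r))
  tr <- numeric(r$length)
  orf0 <- 2L; orf_end <- orf0 + 15L + 2L       # start..stop codon inclusive
  tr[(orf0 + 1):(orf_end + 1)] <- 1
  sm <- smorflist(manual_rocc(tx, list(GS = tr)), shift = 0, utr_side = 5)
  row <- sm[sm$start_pos == orf0, ]
  expect_equal(row$aa_length, 5L)
  expect_equal(row$inframe_reads, 6)
  expect_equal(row$inframe_positions, 6L)
  # excluding the stop codon drops exactly one in-frame position
  sm2 <- smorflist(manual_rocc(tx, list(GS = tr)), shift = 0, utr_side = 5,
                   include_stop = FALSE)
  expect_equal(sm2[sm2$start_pos == orf0, ]$inframe_reads, 5)

  # occupancy only at frame-1 positions counts zero
  tr1 <- numeric(r$length)
  tr1[seq(orf0 + 2, orf_end, by = 3)] <- 2     # 1-based frame-1 slots
  smf <- smorflist(manual_rocc(tx, list(GS = tr1)), shift = 0, utr_side = 5)
  expect_equal(smf[smf$start_pos == orf0, ]$inframe_reads, 0)

  # coverage-mode stores are rejected: frame undefined
  rc <- manual_rocc(tx, list(GS = tr), endmode = "coverage")
  expect_error(smorflist(rc), "coverage")
})
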