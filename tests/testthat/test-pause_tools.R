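# Motif occurrence search, metacodon averaging, pause scores.
# Brute-force oracles live in helper-oracles.R.

test_that("motif occurrences match documented anchor positions", {
  # Pro ("P", CCA) in CDS ATG-CCA-TAA: one hit at the CCA codon
  r <- toy_record("GP", cds_codons = "CCA")
  occ <- find_motif_occurrences(r, "P", kind = 1, frame = 0, utrmode = 1)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$pos, r$cds[1] - 1L + 3L)
  expect_equal(occ$frame, 0L)

  # nucleotide ATG in a "GATGC" 5'UTR, all frames: offset 1
  r2 <- toy_record("GQ", utr5 = "GATGC", cds_codons = "AAA")
  occ2 <- find_motif_occurrences(r2, "ATG", kind = 0, frame = 3, utrmode = 0)
  expect_equal(occ2$pos, 1L)

  # overlapping matches are all reported
  r3 <- toy_record("GR", utr5 = "AAAA", cds_codons = "GGG")
  occ3 <- find_motif_occurrences(r3, "AA", kind = 0, frame = 3, utrmode = 0)
  expect_equal(occ3$pos, 0:2)

  # "f"/"l" prefixes keep only the first / last occurrence
  r4 <- toy_record("GS2", utr5 = "ATGCCATGAATGAA", cds_codons = "AAA")
  f <- find_motif_occurrences(r4, "fATG", kind = 0, utrmode = 0)
  l <- find_motif_occurrences(r4, "lATG", kind = 0, utrmode = 0)
  all3 <- find_motif_occurrences(r4, "ATG", kind = 0, frame = 3, utrmode = 0)
  expect_equal(nrow(all3), 3L)
  expect_equal(f$pos, min(all3$pos))
  expect_equal(l$pos, max(all3$pos))

  expect_error(find_motif_occurrences(r4, "AXG", kind = 0, utrmode = 0),
               "nucleotide")
  expect_error(find_motif_occurrences(r4, "PB", kind = 1, utrmode = 1),
               "amino-acid")
})

test_that("occurrence search equals brute force across motifs, frames and regions", {
  cfg <- sim_config(n_genes = 2, n_reads = 10, seed = 13,
                    cds_range = c(90, 150))
  txs <- make_toy_transcriptome(cfg)
  recs <- c(tiny_txome()$records, txs$records)
  for (rec in recs) {
    for (um in 0:2) {
      for (motif in c("ATG", "CCA", "GG")) for (fr in 0:3) {
        got <- find_motif_occurrences(rec, motif, 0, fr, um)$pos
        expect_equal(got, brute_occurrences(rec, motif, 0, fr, um),
                     info = sprintf("%s nt %s fr%d um%d", rec$gene_id,
                                    motif, fr, um))
      }
      for (motif in c("P", "A", "M", "PP")) for (fr in 0:2) {
        got <- find_motif_occurrences(rec, motif, 1, fr, um)$pos
        expect_equal(got, brute_occurrences(rec, motif, 1, fr, um),
                     info = sprintf("%s aa %s fr%d um%d", rec$gene_id,
                                    motif, fr, um))
      }
    }
  }
})

test_that("the 'all' motif set enumerates 61 sense codons / 20 amino acids", {
  expect_length(riboscope:::expand_motifs("all", 0), 61L)
  expect_length(riboscope:::expand_motifs("all", 1), 20L)
  expect_equal(riboscope:::expand_motifs("P,R,A", 1), c("P", "R", "A"))
  expect_false(any(c("TAA", "TAG", "TGA") %in%
                   riboscope:::expand_motifs("all", 0)))
})

test_that("uniform occupancy gives flat local profiles and pause score 1", {
  cfg <- sim_config(n_genes = 2, n_reads = 10, seed = 17,
                    cds_range = c(150, 210))
  tx <- make_toy_transcriptome(cfg)
  tracks <- lapply(tx$records, function(r) rep(2, r$length))
  rocc <- manual_rocc(tx, tracks)
  res <- posavg(rocc, "A", kind = 1, frame = 0, bkndwindow = 15,
                orfnorm = 0, shift = 0, utrmode = 1)
  prof <- res$profiles[["A"]]
  expect_true(all(abs(prof$mean - prof$mean[1]) < 1e-12))
  expect_equal(res$pause$score[res$pause$motif == "A"], 1)
  # locally normalized windows average to a profile summing to 1
  expect_equal(sum(prof$mean), 1)
})

test_that("the pause score is peak mean over background mean", {
  # window values 1,1,3,9,3,1,1: peak {-1,0,1} mean 5, background mean 1
  r <- toy_record("GK", utr5 = strrep("C", 12),
                  cds_codons = c("AAA", "AAT", "GGG", "AAC", "AAA"),
                  utr3 = strrep("C", 12))
  tx <- toy_transcriptome(list(r))
  p <- regexpr("GGG", r$sequence)[1] - 1L       # 0-based, unique occurrence
  tr <- numeric(r$length)
  tr[(p - 3):(p + 3) + 1L] <- c(1, 1, 3, 9, 3, 1, 1)
  rocc <- manual_rocc(tx, list(GK = tr))
  res <- posavg(rocc, "GGG", kind = 0, frame = 3, bkndwindow = 3,
                orfnorm = 0, shift = 0, utrmode = 1)
  expect_equal(res$pause$n_occurrences, 1L)
  expect_equal(res$pause$score, 5)
  # pause score is invariant under global rescaling of the track
  res2 <- posavg(manual_rocc(tx, list(GK = tr * 37)), "GGG", kind = 0,
                 frame = 3, bkndwindow = 3, orfnorm = 0, shift = 0,
                 utrmode = 1)
  expect_equal(res2$pause$score, res$pause$score)
})

test_that("shift moves occupancy onto the occurrence anchor before averaging", {
  r <- toy_record("GH", utr5 = strrep("A", 20),
                  cds_codons = c("AAA", "CCA", "AAA", "AAA", "AAA"),
                  utr3 = strrep("T", 20))
  tx <- toy_transcriptome(list(r))
  occ <- find_motif_occurrences(r, "P", 1, 0, 1)
  tr <- numeric(r$length)
  tr[occ$pos - 12L + 1L] <- 6                   # 5'-assigned, P site 12 nt down
  res <- posavg(manual_rocc(tx, list(GH = tr)), "P", kind = 1, frame = 0,
                bkndwindow = 6, orfnorm = 0, shift = 12, utrmode = 1)
  prof <- res$profiles[["P"]]
  expect_equal(prof$mean[prof$offset == 0], 1)  # locally normalized spike
  expect_true(all(prof$mean[prof$offset != 0] == 0))
})

test_that("window thresholds and CDS normalization behave as documented", {
  r <- toy_record("GN", utr5 = strrep("A", 30),
                  cds_codons = rep(c("GTT", "CCA", "GTC"), 8),
                  utr3 = strrep("T", 30))
  tx <- toy_transcriptome(list(r))
  u <- rep(4, r$length)                          # uniform density 4
  rocc <- manual_rocc(tx, list(GN = u))
  # CDS-normalized windows: value / mean CDS per-nt density = 1 everywhere
  res <- posavg(rocc, "P", kind = 1, frame = 0, bkndwindow = 8,
                orfnorm = 0.001, shift = 0, utrmode = 1)
  prof <- res$profiles[["P"]]
  expect_true(all(abs(prof$mean - 1) < 1e-12))
  # an unmeetable CDS threshold excludes the gene entirely
  res2 <- posavg(rocc, "P", kind = 1, frame = 0, bkndwindow = 8,
                 orfnorm = 1e9, shift = 0, utrmode = 1)
  expect_equal(res2$pause$n_occurrences, 0L)
  expect_length(res2$profiles, 0L)
  # a window density threshold drops low-coverage occurrences
  res3 <- posavg(rocc, "P", kind = 1, frame = 0, bkndwindowthresh = 1e9,
                 bkndwindow = 8, orfnorm = 0, shift = 0, utrmode = 1)
  expect_equal(res3$pause$n_occurrences, 0L)
})

test_that("posstats scores single occurrences against the region background", {
  r <- toy_record("GT", utr5 = strrep("A", 15),
                  cds_codons = rep(c("GTT", "CCA", "CCG", "GGA", "GTC"), 6),
                  utr3 = strrep("T", 15))
  tx <- toy_transcriptome(list(r))
  u <- rep(1, r$length)
  rocc <- manual_rocc(tx, list(GT = u))
  # uniform occupancy: every score is exactly 1
  st <- posstats(rocc, "PPG", kind = 1, frame = 0, pkwindow = 0, shift = 0,
                 utrmode = 1)
  expect_true(nrow(st) >= 1)
  expect_true(all(st$score == 1))

  # a 10x spike at one PPG anchor scores ~10 with pkwindow 0
  occ <- find_motif_occurrences(r, "PPG", 1, 0, 1)
  tr <- u; tr[occ$pos[1] + 1L] <- 10
  st2 <- posstats(manual_rocc(tx, list(GT = tr)), "PPG", kind = 1, frame = 0,
                  pkwindow = 0, shift = 0, utrmode = 1)
  hit <- st2[st2$pos == occ$pos[1], ]
  # background excludes the peak position, so it stays exactly 1
  expect_equal(hit$background_mean, 1)
  expect_equal(hit$score, 10)

  # absent motif: empty table plus a warning
  expect_warning(st3 <- posstats(rocc, "W", kind = 1, frame = 0,
                                 utrmode = 1),
                 "not found")
  expect_equal(nrow(st3), 0L)
  # gene threshold excludes the whole gene
  expect_warning(st4 <- posstats(rocc, "PPG", kind = 1, genethresh = 1e9,
                                 utrmode = 1))
  expect_equal(nrow(st4), 0L)
})
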