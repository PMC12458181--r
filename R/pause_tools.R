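# Metacodon/metasequence averaging and pause-score statistics.
#
# Occurrence anchoring: offset 0 is the first nt of the motif; users supply
# a shift (12 is typical for 5'-assigned data) to put the P site on the
# anchor. Regions are selected with the utrmode code used throughout the
# CLI: 0 = 5'UTR, 1 = CDS, 2 = 3'UTR.

AA_ALPHABET_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

sense_codons <- function() {
  nts <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  sort(setdiff(all64, STOP_CODONS))
}

utrmode_region <- function(utrmode) {
  switch(as.character(as.integer(utrmode)),
         "0" = "utr5", "1" = "cds", "2" = "utr3",
         stop("utrmode must be 0 (5'UTR), 1 (CDS) or 2 (3'UTR)",
              call. = FALSE))
}

#' Find motif occurrences in one transcript region
#'
#' Nucleotide motifs (\code{kind = 0}) are matched exactly (overlapping
#' matches included) within the chosen region, optionally restricted to
#' one reading frame relative to the CDS start (\code{frame = 3} means all
#' frames). Amino-acid motifs (\code{kind = 1}) are matched against the
#' region's translation in the chosen frame relative to the CDS start
#' (frame 0 = the annotated frame; frames 1/2 translate offset by +1/+2 nt
#' — useful for internal out-of-frame ORF searches); the reported position
#' is the first nucleotide of the first codon of the match. A motif
#' prefixed \code{"f"} or \code{"l"} keeps only the first or last
#' occurrence per gene (nucleotide prefix searches check all frames).
#'
#' @param rec A \code{transcript_record} with sequence.
#' @param motif Motif string, optionally \code{"f"}/\code{"l"}-prefixed.
#' @param kind 0 = nucleotide, 1 = amino acid.
#' @param frame 0/1/2, or 3 for all frames (nucleotide motifs only).
#' @param utrmode 0 = 5'UTR, 1 = CDS, 2 = 3'UTR.
#' @return data.frame: \code{gene_id}, 0-based \code{pos} (first nt of the
#'   occurrence), \code{region}, \code{frame} (relative to CDS start).
#' @export
find_motif_occurrences <- function(rec, motif, kind = 0, frame = 0,
                                   utrmode = 1) {
  stopifnot(kind %in% 0:1)
  region <- utrmode_region(utrmode)
  keep_which <- NULL
  first_chr <- substr(motif, 1, 1)
  if (first_chr %in% c("f", "l")) {
    keep_which <- first_chr
    motif <- substr(motif, 2, nchar(motif))
    if (kind == 0) frame <- 3
  }
  motif <- toupper(motif)
  if (kind == 0) {
    if (!grepl("^[ACGT]+$", motif))
      stop(sprintf("'%s' is not a nucleotide motif (ACGT)", motif),
           call. = FALSE)
    if (!frame %in% 0:3) stop("frame must be 0, 1, 2 or 3", call. = FALSE)
  } else {
    if (!all(strsplit(motif, "")[[1]] %in% AA_ALPHABET_20))
      stop(sprintf("'%s' is not an amino-acid motif", motif), call. = FALSE)
    if (!frame %in% 0:2)
      stop("amino-acid searches use frame 0, 1 or 2", call. = FALSE)
  }
  sp <- rec[[region]]
  empty <- data.frame(gene_id = character(), pos = integer(),
                      region = character(), frame = integer(),
                      stringsAsFactors = FALSE)
  if (span_len(sp) < 1L) return(empty)
  s0 <- sp[1] - 1L; e0 <- sp[2] - 1L                 # 0-based region bounds
  cs <- cds_start0(rec)

  if (kind == 0) {
    if (span_len(sp) < nchar(motif)) return(empty)
    sub <- Biostrings::DNAString(substr(rec$sequence, sp[1], sp[2]))
    hits <- Biostrings::start(Biostrings::matchPattern(motif, sub))
    pos0 <- s0 + hits - 1L
    if (frame %in% 0:2) pos0 <- pos0[(pos0 - cs) %% 3L == frame]
  } else {
    # first in-frame codon start within the region for this frame
    o <- ((cs + frame) - s0) %% 3L
    t0 <- s0 + o
    ncod <- (e0 - t0 + 1L) %/% 3L
    if (ncod < nchar(motif)) return(empty)
    dna <- Biostrings::DNAString(substr(rec$sequence, t0 + 1L,
                                        t0 + 3L * ncod))
    pep <- suppressWarnings(as.character(Biostrings::translate(
      dna, no.init.codon = TRUE, if.fuzzy.codon = "X")))
    hits <- Biostrings::start(Biostrings::matchPattern(
      motif, Biostrings::AAString(pep)))
    pos0 <- t0 + 3L * (hits - 1L)
  }
  if (!length(pos0)) return(empty)
  pos0 <- sort(pos0)
  if (identical(keep_which, "f")) pos0 <- pos0[1]
  if (identical(keep_which, "l")) pos0 <- pos0[length(pos0)]
  data.frame(gene_id = rec$gene_id, pos = as.integer(pos0),
             region = region, frame = as.integer((pos0 - cs) %% 3L),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Expand a motifs argument: comma lists, and "all" -> 20 aa / 61 codons.
expand_motifs <- function(motifs, kind) {
  motifs <- unlist(strsplit(motifs, ",", fixed = TRUE))
  if (length(motifs) == 1L && tolower(motifs) == "all") {
    if (kind == 1) AA_ALPHABET_20 else sense_codons()
  } else motifs
}

#' Metacodon / metasequence averaging with pause scores
#'
#' For every occurrence of each motif, takes the shifted occupancy in a
#' window of \code{bkndwindow} nt on either side of the occurrence's first
#' nucleotide, drops occurrences whose window runs off the transcript or
#' whose window density (store units per kb, with the window length as the
#' kilobase denominator) falls below \code{bkndwindowthresh}, normalizes,
#' and averages the surviving windows position-wise. Under local
#' normalization, windows with zero occupancy carry no density and are
#' dropped rather than averaged in as zeros.
#'
#' Two normalizations are offered: \code{orfnorm = 0} divides each window
#' by its own sum (a local probability density — appropriate when absolute
#' levels vary wildly, e.g. dORFs); \code{orfnorm = v > 0} divides each
#' window by its gene's mean per-nucleotide CDS density, computed with a
#' hard-coded shift of +/-13 nt (sign following the store's end
#' assignment), excluding genes whose CDS density is below \code{v} per kb.
#'
#' A pause score is computed per motif from the averaged profile: the mean
#' over the peak (offsets -1, 0, +1 — a 3-nt window around the occurrence)
#' divided by the mean over the remaining window positions (the background
#' level). With \code{motifs = "all"}, every amino acid (kind 1) or every
#' sense codon (kind 0) is scored.
#'
#' @param rocc A \code{rocc_store} (end-assigned).
#' @param motifs Motif, comma-separated list, or \code{"all"}.
#' @param kind 0 = nucleotide, 1 = amino acid.
#' @param frame Frame relative to CDS start (3 = all, nucleotide only).
#' @param bkndwindowthresh Minimum window density (store units per kb).
#' @param bkndwindow Half-window size, nt (> 0).
#' @param orfnorm 0 = local density; v > 0 = CDS-normalized with CDS
#'   density threshold v.
#' @param shift Integer nt shift toward the ribosome site of interest.
#' @param utrmode 0 = 5'UTR, 1 = CDS, 2 = 3'UTR.
#' @param subset Optional gene subset (vector or CSV path).
#' @return A \code{posavg_result}: list with \code{profiles} (per motif, a
#'   data.frame of \code{offset}/\code{mean}/\code{n}), and \code{pause}
#'   (per motif: \code{n_occurrences}, \code{peak_mean},
#'   \code{background_mean}, \code{score}).
#' @export
posavg <- function(rocc, motifs, kind = 0, frame = 0, bkndwindowthresh = 0,
                   bkndwindow = 30L, orfnorm = 0, shift = 0L, utrmode = 1,
                   subset = NULL) {
  stopifnot(bkndwindow > 0, orfnorm >= 0)
  motifs <- expand_motifs(motifs, kind)
  gids <- resolve_subset(rocc$records, subset)
  w <- as.integer(bkndwindow)
  offsets <- seq.int(-w, w)

  shifted <- lapply(gids, function(g) apply_shift(rocc$tracks[[g]], shift))
  names(shifted) <- gids
  cds_mean_density <- NULL
  if (orfnorm > 0) {
    s13 <- if (identical(rocc$endmode, "3prime")) -13L else 13L
    cds_mean_density <- vapply(gids, function(g) {
      rec <- rocc$records[[g]]
      tr13 <- apply_shift(rocc$tracks[[g]], s13)
      sum(tr13[rec$cds[1]:rec$cds[2]]) / span_len(rec$cds)
    }, 0)
    keep <- cds_mean_density * 1000 >= orfnorm & cds_mean_density > 0
    gids <- gids[keep]
    cds_mean_density <- cds_mean_density[keep]
  }

  profiles <- list()
  pause <- data.frame(motif = motifs, n_occurrences = 0L,
                      peak_mean = NA_real_, background_mean = NA_real_,
                      score = NA_real_, stringsAsFactors = FALSE)
  peak_sel <- offsets %in% (-1):1
  for (mi in seq_along(motifs)) {
    motif <- motifs[mi]
    acc <- numeric(length(offsets))
    nwin <- 0L
    for (g in gids) {
      rec <- rocc$records[[g]]
      occ <- find_motif_occurrences(rec, motif, kind = kind, frame = frame,
                                    utrmode = utrmode)
      if (!nrow(occ)) next
      tr <- shifted[[g]]
      for (p in occ$pos) {
        lo <- p - w; hi <- p + w                    # 0-based
        if (lo < 0L || hi >= rec$length) next       # truncated: drop
        win <- tr[(lo + 1L):(hi + 1L)]
        if (sum(win) / ((2L * w + 1L) / 1000) < bkndwindowthresh) next
        if (orfnorm == 0) {
          s <- sum(win)
          if (s == 0) next              # no density to normalize; drop
          win <- win / s
        } else {
          win <- win / cds_mean_density[[g]]
        }
        acc <- acc + win
        nwin <- nwin + 1L
      }
    }
    pause$n_occurrences[mi] <- nwin
    if (nwin > 0L) {
      prof <- acc / nwin
      profiles[[motif]] <- data.frame(offset = offsets, mean = prof,
                                      n = nwin)
      pk <- mean(prof[peak_sel])
      bk <- mean(prof[!peak_sel])
      pause$peak_mean[mi] <- pk
      pause$background_mean[mi] <- bk
      pause$score[mi] <- if (bk > 0) pk / bk else NA_real_
    }
  }
  structure(list(profiles = profiles, pause = pause,
                 params = list(kind = kind, frame = frame,
                               bkndwindow = w, orfnorm = orfnorm,
                               shift = shift, utrmode = utrmode)),
            class = "posavg_result")
}

#' @export
print.posavg_result <- function(x, ...) {
  cat(sprintf("<posavg_result> %d motif(s), half-window %d nt\n",
              nrow(x$pause), x$params$bkndwindow))
  print(x$pause, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-occurrence pause scores
#'
#' Computes a pause score for every individual occurrence of a motif: the
#' mean shifted occupancy over the occurrence position +/- \code{pkwindow}
#' nt, divided by the mean occupancy over the rest of the analyzed region
#' of that gene (the peak window excluded from the background). Occurrences
#' whose background mean is zero are dropped and tallied. The resulting
#' table supports distribution-level comparisons between motifs.
#'
#' @param rocc A \code{rocc_store}.
#' @param motif A single motif (optionally \code{f}/\code{l}-prefixed).
#' @param kind 0 = nucleotide, 1 = amino acid.
#' @param frame Frame relative to CDS start.
#' @param genethresh Minimum whole-transcript density (store units per kb)
#'   for a gene to be analyzed.
#' @param pkwindow Half-window (nt) of the numerator peak; 0 scores the
#'   single anchor position.
#' @param shift Integer nt shift (positive for 5'-assigned data, negative
#'   for 3'-assigned).
#' @param utrmode 0 = 5'UTR, 1 = CDS, 2 = 3'UTR.
#' @return data.frame with one row per retained occurrence: \code{gene_id},
#'   \code{pos}, \code{peak_mean}, \code{background_mean}, \code{score};
#'   attribute \code{"dropped_zero_background"} tallies discarded
#'   occurrences.
#' @export
posstats <- function(rocc, motif, kind = 0, frame = 0, genethresh = 0,
                     pkwindow = 1L, shift = 0L, utrmode = 1) {
  stopifnot(pkwindow >= 0)
  pk <- as.integer(pkwindow)
  region <- utrmode_region(utrmode)
  gids <- names(rocc$records)
  gids <- gids[vapply(gids, function(g) gene_rpkm(rocc, g) >= genethresh,
                      TRUE)]
  rows <- list()
  dropped <- 0L
  found_any <- FALSE
  for (g in gids) {
    rec <- rocc$records[[g]]
    occ <- find_motif_occurrences(rec, motif, kind = kind, frame = frame,
                                  utrmode = utrmode)
    if (!nrow(occ)) next
    found_any <- TRUE
    tr <- apply_shift(rocc$tracks[[g]], shift)
    sp <- rec[[region]]
    region_idx <- sp[1]:sp[2]                        # 1-based
    for (p in occ$pos) {
      pk_idx <- (p - pk):(p + pk) + 1L
      pk_idx <- pk_idx[pk_idx >= 1L & pk_idx <= rec$length]
      bg_idx <- setdiff(region_idx, pk_idx)
      if (!length(bg_idx)) next
      bg <- mean(tr[bg_idx])
      if (bg == 0) { dropped <- dropped + 1L; next }
      pm <- mean(tr[pk_idx])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, pos = p, peak_mean = pm, background_mean = bg,
        score = pm / bg, stringsAsFactors = FALSE)
    }
  }
  if (!found_any)
    warning(sprintf("motif '%s' not found in any analyzed transcript", motif),
            call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), pos = integer(), peak_mean = numeric(),
               background_mean = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "dropped_zero_background") <- dropped
  out
}
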