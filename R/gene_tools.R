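# Per-gene outputs: position tracks, region/frame quantitation, and
# uORF/dORF discovery with in-frame read counting.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Shift an occupancy track toward an internal ribosome site
#'
#' End-assigned occupancy is offset so counts line up with an internal
#' position of the ribosome (e.g. the P site, typically 12 nt downstream of
#' a 28-nt footprint's 5' end). The value at 0-based position \code{p}
#' moves to \code{p + shift}; use a positive shift for 5'-assigned data and
#' a negative shift for 3'-assigned data. Values shifted outside the
#' transcript are discarded, not wrapped.
#'
#' @param values Numeric occupancy vector (one value per nucleotide).
#' @param shift Integer offset in nt.
#' @return Shifted numeric vector of the same length, with attribute
#'   \code{"dropped"} = sum of the discarded values.
#' @export
apply_shift <- function(values, shift) {
  shift <- as.integer(shift)
  n <- length(values)
  if (shift == 0L || n == 0L) {
    attr(values, "dropped") <- 0
    return(values)
  }
  out <- numeric(n)
  if (shift > 0L) {
    keep <- n - min(shift, n)
    if (keep > 0) out[(shift + 1L):n] <- values[1:keep]
    dropped <- sum(values[seq_len(n) > keep])
  } else {
    s <- min(-shift, n)
    keep <- n - s
    if (keep > 0) out[1:keep] <- values[(s + 1L):n]
    dropped <- sum(values[seq_len(min(s, n))])
  }
  attr(out, "dropped") <- dropped
  out
}

rocc_as_list <- function(rocc) {
  if (inherits(rocc, "rocc_store")) list(rocc = rocc) else rocc
}

#' Per-position occupancy table for one or more genes
#'
#' Writes the occupancy (in the store's units, typically RPM) at every
#' transcript position of the requested genes, one column per input store —
#' a faithful per-nucleotide export that avoids the windowing/averaging
#' artifacts genome browsers introduce when rendering long transcripts.
#'
#' @param rocc A \code{rocc_store} or a named list of them (one output
#'   column each).
#' @param gene_names Character vector of gene ids or aliases.
#' @return data.frame with columns \code{gene}, \code{position} (1-based),
#'   and one value column per store.
#' @export
writegene2 <- function(rocc, gene_names) {
  stores <- rocc_as_list(rocc)
  if (is.null(names(stores)) || any(!nzchar(names(stores))))
    names(stores) <- paste0("sample", seq_along(stores))
  ref <- stores[[1]]
  out <- list()
  for (nm in gene_names) {
    gid <- resolve_gene(list(records = ref$records), nm)
    n <- ref$records[[gid]]$length
    df <- data.frame(gene = gid, position = seq_len(n))
    for (s in names(stores)) {
      tr <- stores[[s]]$tracks[[gid]]
      if (is.null(tr))
        stop(sprintf("gene '%s' absent from store '%s'", gid, s),
             call. = FALSE)
      df[[s]] <- tr
    }
    out[[nm]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Convert a sum in store units back to raw read counts.
to_raw <- function(x, rocc) {
  if (identical(rocc$units, "rpm")) x * rocc$denominator / 1e6 else x
}

#' Region and reading-frame quantitation per gene
#'
#' After shifting occupancy toward the ribosome site of interest, sums each
#' transcript's 5'UTR, CDS and 3'UTR occupancy. Raw read counts (for
#' differential-expression tools) and length-normalized RPKM
#' (reads per kilobase per million mapped) are both reported. With
#' \code{doextra}, CDS occupancy is additionally split by reading frame,
#' where frame of position \code{p} is \code{(p - cds_start) mod 3} —
#' a direct readout of 3-nt periodicity and frame defects.
#'
#' @param rocc A \code{rocc_store}.
#' @param shift Integer nt shift applied before counting (12 typically
#'   aligns 5'-assigned data with the P site).
#' @param doextra Logical or 0/1: add per-frame CDS columns.
#' @return data.frame with one row per gene: raw counts and RPKM per
#'   region, frame sums (store units) when requested, and the shift-dropped
#'   tally. Zero-length regions report RPKM 0 and are flagged in
#'   \code{empty_region}.
#' @export
genelist <- function(rocc, shift = 0L, doextra = FALSE) {
  doextra <- as.logical(as.integer(doextra))
  recs <- rocc$records
  n <- length(recs)
  regions <- c("utr5", "cds", "utr3")
  sums <- matrix(0, n, 3, dimnames = list(names(recs), regions))
  frames <- matrix(0, n, 3)
  dropped <- numeric(n)
  lens <- matrix(0L, n, 3, dimnames = list(NULL, regions))
  for (i in seq_len(n)) {
    rec <- recs[[i]]
    tr <- apply_shift(rocc$tracks[[rec$gene_id]], shift)
    dropped[i] <- attr(tr, "dropped")
    for (j in 1:3) {
      sp <- rec[[regions[j]]]
      lens[i, j] <- span_len(sp)
      if (lens[i, j] > 0L) sums[i, j] <- sum(tr[sp[1]:sp[2]])
    }
    if (doextra) {
      cds_pos <- rec$cds[1]:rec$cds[2]                    # 1-based
      fr <- (cds_pos - rec$cds[1]) %% 3L
      frames[i, ] <- vapply(0:2, function(f) sum(tr[cds_pos[fr == f]]), 0)
    }
  }
  raw <- to_raw(sums, rocc)
  rpkm <- ifelse(lens > 0L, sums / (lens / 1000), 0)
  out <- data.frame(
    gene_id = names(recs),
    alias = vapply(recs, `[[`, "", "alias"),
    utr5_raw = raw[, 1], cds_raw = raw[, 2], utr3_raw = raw[, 3],
    utr5_rpkm = rpkm[, 1], cds_rpkm = rpkm[, 2], utr3_rpkm = rpkm[, 3],
    shift_dropped = to_raw(dropped, rocc),
    empty_region = rowSums(lens == 0L) > 0L,
    row.names = NULL, stringsAsFactors = FALSE)
  if (doextra) {
    fr_raw <- to_raw(frames, rocc)
    out$frame0 <- fr_raw[, 1]; out$frame1 <- fr_raw[, 2]; out$frame2 <- fr_raw[, 3]
  }
  out
}

# All codons at Hamming distance <= 1 from ATG (ATG itself included).
near_cognate_codons <- function() {
  base <- c("A", "T", "G")
  out <- "ATG"
  for (i in 1:3) for (b in c("A", "C", "G", "T")) {
    cand <- base; cand[i] <- b
    out <- c(out, paste(cand, collapse = ""))
  }
  unique(out)
}

#' Find candidate small ORFs in a UTR
#'
#' Scans the stated UTR for start codons — ATG only, or additionally the
#' nine near-cognate codons one substitution away — and extends each in
#' frame to the first stop codon (TAA/TAG/TGA), searching past the UTR
#' boundary to the transcript end. ORFs with no stop are discarded. Among
#' ORFs sharing a stop codon, \code{smallest = 1} keeps the one from the
#' last (most downstream) start, \code{smallest = 0} the first.
#'
#' @param rec A \code{transcript_record} with sequence.
#' @param utr_side 5 or 3: scan the 5'UTR (uORFs) or 3'UTR (dORFs).
#' @param mismatches 0 = ATG starts only; 1 = allow one mismatch (near-
#'   cognate starts).
#' @param smallest Among same-stop ORFs, keep the smallest (1) or
#'   longest (0).
#' @param lengththresh Amino-acid length filter: \code{k > 0} keeps ORFs
#'   strictly longer than \code{k}; \code{k < 0} keeps ORFs of length
#'   exactly \code{|k|}; 0 keeps all.
#' @return data.frame, one row per ORF: \code{gene_id}, \code{utr_side},
#'   0-based \code{start_pos} and \code{stop_pos} (first nt of start/stop
#'   codon), \code{start_codon}, \code{aa_length} (start Met counted, stop
#'   excluded).
#' @export
find_smorfs <- function(rec, utr_side = 5, mismatches = 0, smallest = 1,
                        lengththresh = 0) {
  stopifnot(utr_side %in% c(5, 3), mismatches %in% 0:1, smallest %in% 0:1)
  region <- if (utr_side == 5) rec$utr5 else rec$utr3
  empty <- data.frame(gene_id = character(), utr_side = integer(),
                      start_pos = integer(), stop_pos = integer(),
                      start_codon = character(), aa_length = integer(),
                      stringsAsFactors = FALSE)
  if (span_len(region) < 3L) return(empty)
  seq <- rec$sequence
  starts_ok <- if (mismatches == 1) near_cognate_codons() else "ATG"
  # candidate start codons wholly inside the UTR (0-based positions)
  cand0 <- (region[1] - 1L):(region[2] - 3L)
  codons <- substring(seq, cand0 + 1L, cand0 + 3L)
  cand0 <- cand0[codons %in% starts_ok]
  if (!length(cand0)) return(empty)

  orfs <- list()
  for (p in cand0) {
    q <- p
    stop_at <- NA_integer_
    while (q + 3L <= nchar(seq)) {
      if (substring(seq, q + 1L, q + 3L) %in% STOP_CODONS && q > p) {
        stop_at <- q; break
      }
      # the start codon itself is never a stop (disjoint sets), but guard q > p
      if (q == p && substring(seq, q + 1L, q + 3L) %in% STOP_CODONS) break
      q <- q + 3L
    }
    if (!is.na(stop_at))
      orfs[[length(orfs) + 1L]] <- c(start = p, stop = stop_at)
  }
  if (!length(orfs)) return(empty)
  m <- do.call(rbind, orfs)
  df <- data.frame(start_pos = m[, "start"], stop_pos = m[, "stop"])
  # one ORF per stop codon
  pick <- tapply(df$start_pos, df$stop_pos,
                 if (smallest == 1) max else min)
  df <- data.frame(start_pos = as.integer(pick),
                   stop_pos = as.integer(names(pick)))
  df$aa_length <- (df$stop_pos - df$start_pos) %/% 3L
  if (lengththresh > 0) df <- df[df$aa_length > lengththresh, , drop = FALSE]
  if (lengththresh < 0) df <- df[df$aa_length == -lengththresh, , drop = FALSE]
  if (!nrow(df)) return(empty)
  df <- df[order(df$start_pos), , drop = FALSE]
  data.frame(gene_id = rec$gene_id, utr_side = as.integer(utr_side),
             start_pos = df$start_pos, stop_pos = df$stop_pos,
             start_codon = substring(seq, df$start_pos + 1L, df$start_pos + 3L),
             aa_length = df$aa_length,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Small-ORF discovery with in-frame read counting
#'
#' Runs [find_smorfs()] on every transcript and counts shifted occupancy at
#' in-frame positions only — positions \code{p} with
#' \code{(p - start_pos) mod 3 = 0} from the start codon through (by
#' default) the stop codon's first position — so reads from overlapping
#' out-of-frame ORFs are largely excluded. The gene's CDS occupancy is
#' reported alongside for density comparisons.
#'
#' @inheritParams find_smorfs
#' @param rocc An end-assigned \code{rocc_store} (coverage mode has no
#'   defined reading frame and is an error).
#' @param shift Integer nt shift toward the ribosome site of interest.
#' @param include_stop Count the stop codon's first in-frame position
#'   (terminating ribosomes are real occupancy); default \code{TRUE}.
#' @return data.frame: one row per ORF with \code{inframe_reads} (store
#'   units), \code{inframe_positions}, and the gene's \code{cds_sum} and
#'   \code{cds_rpkm}.
#' @export
smorflist <- function(rocc, lengththresh = 0, shift = 0L, smallest = 1,
                      mismatches = 0, utr_side = 5, include_stop = TRUE) {
  if (identical(rocc$endmode, "coverage"))
    stop("smorflist needs an end-assigned store; reading frame is undefined for coverage mode",
         call. = FALSE)
  out <- list()
  for (rec in rocc$records) {
    orfs <- find_smorfs(rec, utr_side = utr_side, mismatches = mismatches,
                        smallest = smallest, lengththresh = lengththresh)
    if (!nrow(orfs)) next
    tr <- apply_shift(rocc$tracks[[rec$gene_id]], shift)
    cds_sum <- sum(tr[rec$cds[1]:rec$cds[2]])
    cds_rpkm <- cds_sum / (span_len(rec$cds) / 1000)
    last <- if (include_stop) orfs$stop_pos else orfs$stop_pos - 3L
    orfs$inframe_reads <- mapply(function(s, e) {
      if (e < s) return(0)
      sum(tr[seq.int(s, e, by = 3L) + 1L])
    }, orfs$start_pos, last)
    orfs$inframe_positions <- pmax(0L, (last - orfs$start_pos) %/% 3L + 1L)
    orfs$cds_sum <- cds_sum
    orfs$cds_rpkm <- cds_rpkm
    out[[rec$gene_id]] <- orfs
  }
  if (!length(out))
    return(data.frame(gene_id = character(), utr_side = integer(),
                      start_pos = integer(), stop_pos = integer(),
                      start_codon = character(), aa_length = integer(),
                      inframe_reads = numeric(), inframe_positions = integer(),
                      cds_sum = numeric(), cds_rpkm = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
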