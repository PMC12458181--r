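# Population-level profiles: region/length histograms, start/stop
# metagenes, and read-length-resolved (3D) metagenes.

#' Footprint length distribution by transcript region
#'
#' Assigns each retained read (by its raw, unshifted 5' end) to exactly one
#' of five regions: \code{start} if the 5' end lies within \code{window} nt
#' of the start codon's first nucleotide, \code{stop} analogously around
#' the stop codon's first nucleotide (start takes precedence), otherwise
#' the annotated region (5'UTR / CDS / 3'UTR) containing the 5' end. Three
#' views are computed: a per-region read-length probability density, each
#' region's share of total reads, and a length-normalized share in which
#' each read is weighted by the reciprocal of its own gene's region length
#' so short, densely covered regions (start/stop) are not swamped.
#'
#' @param sam Path to a SAM file, or the result of [read_alignments()].
#' @param txome A \code{transcriptome}.
#' @param smallsize,largesize Inclusive read-length window (nt).
#' @param window Half-window (nt) around the start/stop codon first
#'   nucleotide defining the \code{start} and \code{stop} regions.
#' @param subset Optional gene subset: character vector, or path to a CSV
#'   with a \code{genenames} column; \code{"none"}/\code{NULL} = all genes.
#' @return A \code{region_length_histogram}: list with \code{counts}
#'   (region x length matrix), \code{density} (rows summing to 1 where
#'   nonempty), \code{abundance_share}, \code{length_norm_share},
#'   \code{total_reads}, and the parameters used.
#' @export
region_size_and_abundance <- function(sam, txome, smallsize, largesize,
                                      window = 4L, subset = NULL) {
  stopifnot(window >= 0)
  aln <- if (is.character(sam)) read_alignments(sam, txome) else sam
  reads <- aln$reads
  keep_genes <- resolve_subset(txome$records, subset)
  reads <- reads[reads$read_length >= smallsize &
                 reads$read_length <= largesize &
                 reads$gene_id %in% keep_genes, , drop = FALSE]

  regions <- c("utr5", "start", "cds", "stop", "utr3")
  lengths <- smallsize:largesize
  counts <- matrix(0, length(regions), length(lengths),
                   dimnames = list(regions, lengths))
  wsum <- setNames(numeric(5), regions)
  recs <- txome$records
  cs <- vapply(recs, cds_start0, 0L)
  ss <- vapply(recs, stop_start0, 0L)
  u5e <- vapply(recs, function(r) r$utr5[2], 0L)   # 1-based end; 0 if empty
  ce  <- vapply(recs, function(r) r$cds[2], 0L)
  u5len <- vapply(recs, function(r) span_len(r$utr5), 0L)
  cdslen <- vapply(recs, function(r) span_len(r$cds), 0L)
  u3len <- vapply(recs, function(r) span_len(r$utr3), 0L)

  if (nrow(reads)) {
    g <- reads$gene_id
    e5 <- reads$left
    reg <- ifelse(abs(e5 - cs[g]) <= window, "start",
           ifelse(abs(e5 - ss[g]) <= window, "stop",
           ifelse(e5 <= u5e[g] - 1L, "utr5",
           ifelse(e5 <= ce[g] - 1L, "cds", "utr3"))))
    reglen <- ifelse(reg %in% c("start", "stop"), 2 * window + 1,
              ifelse(reg == "utr5", u5len[g],
              ifelse(reg == "cds", cdslen[g], u3len[g])))
    tab <- table(factor(reg, levels = regions),
                 factor(reads$read_length, levels = lengths))
    counts[] <- as.numeric(tab)
    w <- ifelse(reglen > 0, 1 / reglen, 0)
    ws <- tapply(w, factor(reg, levels = regions), sum, default = 0)
    wsum[] <- as.numeric(ws)
  }

  totals <- rowSums(counts)
  density <- counts
  nz <- totals > 0
  density[nz, ] <- counts[nz, , drop = FALSE] / totals[nz]
  abundance <- if (sum(totals) > 0) totals / sum(totals) else totals
  lnorm <- if (sum(wsum) > 0) wsum / sum(wsum) else wsum

  structure(list(counts = counts, density = density,
                 abundance_share = abundance, length_norm_share = lnorm,
                 total_reads = sum(totals),
                 smallsize = smallsize, largesize = largesize,
                 window = window),
            class = "region_length_histogram")
}

#' @export
print.region_length_histogram <- function(x, ...) {
  cat(sprintf("<region_length_histogram> %d reads, lengths %d-%d nt, window +/-%d nt\n",
              x$total_reads, x$smallsize, x$largesize, x$window))
  print(round(rbind(`read share` = x$abundance_share,
                    `per-length share` = x$length_norm_share), 4))
  invisible(x)
}

#' Metagene average at start or stop codons
#'
#' Averages occupancy across transcripts aligned at a common anchor: the
#' first nucleotide of the start codon (\code{kind = 1}) or of the stop
#' codon (\code{kind = 2}), at offset 0. Negative offsets are upstream.
#' With \code{weighting = 0} the per-offset arithmetic mean of the stored
#' values (RPM) is taken, so highly expressed genes dominate; with
#' \code{weighting = 1} each gene's track is first divided by its total CDS
#' occupancy, so every gene contributes equally ("fraction of CDS reads"
#' units) — genes with zero CDS occupancy are excluded. At each offset only
#' genes whose transcript actually covers that offset enter the mean.
#'
#' @param rocc A \code{rocc_store}.
#' @param kind 1 = start codon, 2 = stop codon.
#' @param weighting 0 = plain RPM mean; 1 = gene-equal weighting.
#' @param genethresh Minimum whole-transcript density (store units per kb)
#'   for a gene to be included.
#' @param range5,range3 Extent (nt) upstream / downstream of the anchor.
#' @param subset Optional gene subset (vector or CSV path).
#' @return A \code{meta_profile} data.frame: \code{offset}, \code{mean},
#'   \code{n_genes}, with the weighting and eligible-gene count as
#'   attributes.
#' @export
metagene <- function(rocc, kind = 1, weighting = 0, genethresh = 0,
                     range5 = 50L, range3 = 300L, subset = NULL) {
  stopifnot(kind %in% 1:2, weighting %in% 0:1, genethresh >= 0)
  gids <- resolve_subset(rocc$records, subset)
  gids <- gids[vapply(gids, function(g) gene_rpkm(rocc, g) >= genethresh,
                      TRUE)]
  tracks <- rocc$tracks[gids]
  if (weighting == 1) {
    cds_tot <- vapply(gids, function(g) {
      rec <- rocc$records[[g]]
      sum(rocc$tracks[[g]][rec$cds[1]:rec$cds[2]])
    }, 0)
    gids <- gids[cds_tot > 0]
    tracks <- Map(`/`, rocc$tracks[gids], cds_tot[cds_tot > 0])
  }
  if (!length(gids))
    stop("no genes eligible for metagene (check genethresh and subset)",
         call. = FALSE)
  anchor <- vapply(gids, function(g) {
    rec <- rocc$records[[g]]
    if (kind == 1) cds_start0(rec) else stop_start0(rec)
  }, 0L)
  lens <- vapply(gids, function(g) rocc$records[[g]]$length, 0L)
  offsets <- seq.int(-range5, range3)
  sums <- numeric(length(offsets))
  ngen <- integer(length(offsets))
  for (i in seq_along(gids)) {
    pos <- anchor[i] + offsets              # 0-based transcript positions
    ok <- pos >= 0L & pos < lens[i]
    sums[ok] <- sums[ok] + tracks[[i]][pos[ok] + 1L]
    ngen[ok] <- ngen[ok] + 1L
  }
  out <- data.frame(offset = offsets,
                    mean = ifelse(ngen > 0, sums / ngen, 0),
                    n_genes = ngen)
  attr(out, "weighting") <- weighting
  attr(out, "kind") <- c("start", "stop")[kind]
  attr(out, "eligible_genes") <- length(gids)
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Read-length-resolved (3D) metagene
#'
#' Builds a read-length x offset count matrix around the start or stop
#' codon, working directly on the SAM file (occupancy stores collapse read
#' length). For each retained read of length L in the size window, the
#' assigned end (5' or 3') defines an offset from the anchor; the cell
#' (L, offset) is incremented and all cells are finally scaled to RPM with
#' the same whole-file denominator rule as [build_rocc()]. The column sums
#' form the matching conventional metagene and are returned as
#' \code{marginal}.
#'
#' @param sam Path to a SAM file, or the result of [read_alignments()].
#' @param txome A \code{transcriptome}.
#' @param smallsize,largesize Inclusive read-length window (nt).
#' @param window_left,window_right Extent (nt) upstream / downstream of the
#'   anchor.
#' @param anchor_kind 1 = start codon, 2 = stop codon.
#' @param end_assignment \code{"5prime"} or \code{"3prime"}.
#' @param subset Optional gene subset (vector or CSV path).
#' @return A \code{meta3d_matrix}: list with \code{matrix} (lengths x
#'   offsets, RPM), \code{marginal} (column sums), \code{lengths},
#'   \code{offsets}.
#' @export
metagene_3d <- function(sam, txome, smallsize, largesize,
                        window_left = 200L, window_right = 200L,
                        anchor_kind = 1, end_assignment = c("5prime", "3prime"),
                        subset = NULL) {
  end_assignment <- match.arg(end_assignment)
  stopifnot(anchor_kind %in% 1:2)
  aln <- if (is.character(sam)) read_alignments(sam, txome) else sam
  denom <- aln$tallies[["retained"]]
  reads <- aln$reads
  keep_genes <- resolve_subset(txome$records, subset)
  reads <- reads[reads$read_length >= smallsize &
                 reads$read_length <= largesize &
                 reads$gene_id %in% keep_genes, , drop = FALSE]
  lengths <- smallsize:largesize
  offsets <- seq.int(-window_left, window_right)
  m <- matrix(0, length(lengths), length(offsets),
              dimnames = list(lengths, offsets))
  if (nrow(reads)) {
    anchor <- vapply(txome$records, function(r)
      if (anchor_kind == 1) cds_start0(r) else stop_start0(r), 0L)
    end <- if (end_assignment == "5prime") reads$left
           else reads$left + reads$read_length - 1L
    off <- end - anchor[reads$gene_id]
    ok <- off >= -window_left & off <= window_right
    if (any(ok)) {
      tab <- table(factor(reads$read_length[ok], levels = lengths),
                   factor(off[ok], levels = offsets))
      m[] <- as.numeric(tab)
    }
  }
  if (all(m == 0))
    warning("3D metagene window captured no reads", call. = FALSE)
  if (denom > 0) m <- m * 1e6 / denom
  structure(list(matrix = m, marginal = colSums(m),
                 lengths = lengths, offsets = offsets,
                 end_assignment = end_assignment,
                 anchor = c("start", "stop")[anchor_kind],
                 denominator = denom),
            class = "meta3d_matrix")
}

#' @export
print.meta3d_matrix <- function(x, ...) {
  cat(sprintf("<meta3d_matrix> %s-assigned, anchored at %s codon; lengths %d-%d nt, offsets %d..%d\n",
              x$end_assignment, x$anchor, min(x$lengths), max(x$lengths),
              min(x$offsets), max(x$offsets)))
  cat(sprintf("  total %.2f rpm across %d cells\n", sum(x$matrix),
              length(x$matrix)))
  invisible(x)
}

#' Plot a metagene profile
#'
#' @param x A \code{meta_profile} from [metagene()].
#' @param ... Passed to [plot()].
#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$offset, x$mean, type = "h",
       xlab = sprintf("offset from %s codon (nt)", attr(x, "kind")),
       ylab = if (attr(x, "weighting") == 1) "mean fraction of CDS reads"
              else "mean RPM", ...)
  invisible(x)
}

#' Plot a 3D metagene as a heatmap
#'
#' @param x A \code{meta3d_matrix} from [metagene_3d()].
#' @param ... Passed to [image()].
#' @export
plot.meta3d_matrix <- function(x, ...) {
  graphics::image(x = x$offsets, y = x$lengths, z = t(x$matrix),
        col = grDevices::hcl.colors(64, "viridis"),
        xlab = sprintf("offset from %s codon (nt)", x$anchor),
        ylab = "read length (nt)", ...)
  invisible(x)
}
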