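# Exhaustive transcriptome-derived read generation and exact-match
# multimapping diagnostics. A deterministic k-mer index over the forward
# strand replaces an external two-pass aligner workflow for 0-mismatch
# questions: how many places can a read of length k map, and which
# transcript positions are non-unique?

MM_CAP <- 100000L

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Build an exact-match k-mer index over a transcriptome
#'
#' Indexes every length-\code{k} window of every transcript's forward
#' strand (the transcriptome is sense-only). The index may be built in
#' gene-partitioned passes (\code{chunk_size} genes at a time) whose merged
#' result is identical to the single-pass result — counting is associative
#' — which bounds memory on large inputs.
#'
#' @param txome A \code{transcriptome}.
#' @param k Read length (nt), >= 1.
#' @param revcomp Also index reverse-complement windows (antisense
#'   sensitivity comparison); off by default.
#' @param chunk_size Genes per pass; default all in one pass.
#' @param store_sites Keep the full k-mer -> (gene, position) table (memory
#'   heavy; used for audits).
#' @return A \code{kmer_index}: list with \code{k}, \code{counts} (named
#'   integer vector, occurrences per k-mer), \code{total_postings},
#'   \code{skipped} (transcripts shorter than k), and optionally
#'   \code{sites}.
#' @export
build_kmer_index <- function(txome, k, revcomp = FALSE, chunk_size = Inf,
                             store_sites = FALSE) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  gids <- names(txome$records)
  lens <- vapply(txome$records, `[[`, 0L, "length")
  use <- gids[lens >= k]
  skipped <- sum(lens < k)
  counts <- integer(0)
  sites <- if (store_sites) list() else NULL
  chunks <- split(use, ceiling(seq_along(use) / min(chunk_size, length(use))))
  for (chunk in chunks) {
    kmers <- character(0); rc <- character(0)
    genes <- character(0); poss <- integer(0)
    for (g in chunk) {
      seq <- txome$records[[g]]$sequence
      n <- nchar(seq) - k + 1L
      km <- substring(seq, 1:n, k:(k + n - 1L))
      kmers <- c(kmers, km)
      if (store_sites) {
        genes <- c(genes, rep(g, n)); poss <- c(poss, 0:(n - 1L))
      }
      if (revcomp) rc <- c(rc, revcomp_chr(km))
    }
    tab <- table(c(kmers, rc))
    add <- setNames(as.integer(tab), names(tab))
    common <- intersect(names(counts), names(add))
    counts[common] <- counts[common] + add[common]
    counts <- c(counts, add[setdiff(names(add), names(counts))])
    if (store_sites)
      sites[[length(sites) + 1L]] <-
        data.frame(kmer = kmers[seq_along(genes)], gene_id = genes,
                   pos = poss, stringsAsFactors = FALSE)
  }
  structure(list(k = k, counts = counts,
                 total_postings = sum(pmax(lens - k + 1L, 0L)) *
                   (1L + as.integer(revcomp)),
                 revcomp = revcomp, skipped = skipped,
                 sites = if (store_sites) do.call(rbind, sites) else NULL),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d distinct k-mers, %d postings%s\n",
              x$k, length(x$counts), x$total_postings,
              if (x$revcomp) " (+revcomp)" else ""))
  invisible(x)
}

#' Generate every possible read from a transcriptome
#'
#' Emits, for each transcript of length L >= k, the L - k + 1 reads
#' starting at each position — a full-coverage read set used to probe how
#' read length determines mapping uniqueness. Reads are deterministically
#' named \code{gene_id:position} (0-based) with a constant quality line.
#'
#' @param txome A \code{transcriptome}.
#' @param k Read length (nt).
#' @param path Optional FASTQ output path.
#' @return Named character vector of read sequences (names are read ids),
#'   with attribute \code{"skipped"} = number of transcripts shorter than
#'   k. Written as FASTQ when \code{path} is given.
#' @export
generate_fullcov_reads <- function(txome, k, path = NULL) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  out <- list()
  skipped <- 0L
  for (rec in txome$records) {
    n <- rec$length - k + 1L
    if (n < 1L) { skipped <- skipped + 1L; next }
    reads <- substring(rec$sequence, 1:n, k:(k + n - 1L))
    names(reads) <- sprintf("%s:%d", rec$gene_id, 0:(n - 1L))
    out[[rec$gene_id]] <- reads
  }
  reads <- if (length(out)) unlist(out, use.names = TRUE) else
    stats::setNames(character(0), character(0))
  if (length(out)) names(reads) <- unlist(lapply(out, names), use.names = FALSE)
  attr(reads, "skipped") <- skipped
  if (!is.null(path)) {
    qual <- strrep("I", k)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  }
  reads
}

#' Classify reads by exact-match site count
#'
#' Looks every read up in the k-mer index and reports how many transcriptome
#' sites it matches exactly: unique (1 site), multimapped (>= 2), or
#' unmapped (0 — impossible for reads generated from the indexed
#' transcriptome itself, since each maps at least to its source).
#'
#' @param index A \code{kmer_index}.
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @return List: \code{site_counts} (integer per read), \code{n},
#'   \code{mapped_fraction}, \code{unique_fraction},
#'   \code{multimapped_fraction}.
#' @export
classify_reads <- function(index, reads) {
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.f(ast)?q$", reads, ignore.case = TRUE)) {
    rs <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- as.character(rs)
  }
  if (any(nchar(reads) != index$k))
    stop(sprintf("all reads must have length k=%d to match the index",
                 index$k), call. = FALSE)
  sc <- index$counts[reads]
  sc[is.na(sc)] <- 0L
  sc <- unname(as.integer(sc))
  n <- length(sc)
  list(site_counts = sc, n = n,
       mapped_fraction = mean(sc >= 1L),
       unique_fraction = mean(sc == 1L),
       multimapped_fraction = mean(sc >= 2L))
}

#' Multimapper-identifier tracks
#'
#' For every transcript position p whose length-\code{k} window fits, the
#' track value is the number of exact-match sites of that window when it is
#' 2 or more (capped at 100,000), and 0 where the window maps uniquely —
#' a browser-ready flag for regions where short-read mapping is ambiguous.
#'
#' @param txome A \code{transcriptome}.
#' @param k Read length (nt).
#' @param path Optional BEDGRAPH output (0-based half-open, adjacent equal
#'   values merged, zero positions omitted).
#' @param index Optional prebuilt \code{kmer_index} at this k.
#' @return A \code{multimap_track_set}: list with \code{tracks} (named
#'   list of integer vectors, one per transcript) and \code{k}.
#' @export
mm_id_track <- function(txome, k, path = NULL, index = NULL) {
  if (is.null(index)) index <- build_kmer_index(txome, k)
  stopifnot(index$k == k)
  tracks <- lapply(txome$records, function(rec) {
    v <- integer(rec$length)
    n <- rec$length - k + 1L
    if (n >= 1L) {
      km <- substring(rec$sequence, 1:n, k:(k + n - 1L))
      cnt <- unname(index$counts[km])
      cnt[is.na(cnt)] <- 0L
      cnt <- pmin(as.integer(cnt), MM_CAP)
      cnt[cnt < 2L] <- 0L
      v[1:n] <- cnt
    }
    v
  })
  out <- structure(list(tracks = tracks, k = as.integer(k)),
                   class = "multimap_track_set")
  if (!is.null(path)) write_bedgraph(tracks, path)
  out
}

#' @export
print.multimap_track_set <- function(x, ...) {
  nz <- sum(vapply(x$tracks, function(v) sum(v > 0L), 0L))
  cat(sprintf("<multimap_track_set> k=%d, %d transcripts, %d multimapping positions\n",
              x$k, length(x$tracks), nz))
  invisible(x)
}
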