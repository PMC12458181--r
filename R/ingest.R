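# SAM ingestion and the per-transcript occupancy store ("ROCC").
#
# Reference names in the SAM are gene ids (shortnames FASTA dialect).
# All internal coordinates are 0-based; `left` is the leftmost aligned
# transcript position. Read length is the reference span of the alignment
# (soft-clipped bases excluded), so end assignment is alignment-derived.

ROCC_FORMAT_VERSION <- 1L

#' Read and filter transcriptome alignments from a SAM file
#'
#' Retains records that are mapped, forward-strand, and neither secondary
#' nor supplementary; everything else is tallied by reason. With
#' \code{paired = TRUE}, properly-paired mates are collapsed to one fragment
#' spanning the outer mate coordinates.
#'
#' @param sam_path Path to a SAM (or BAM) file aligned to the shortnames
#'   transcriptome, so reference names are gene ids.
#' @param txome A \code{transcriptome}; unknown reference names are an error.
#' @param paired Collapse properly-paired reads into fragments (default off).
#' @return List with \code{reads} — data.frame(\code{gene_id}, \code{left}
#'   (0-based), \code{read_length}) — and \code{tallies}, a named integer
#'   vector (total, retained, unmapped, reverse, secondary, supplementary).
#' @export
read_alignments <- function(sam_path, txome, paired = FALSE) {
  bam <- if (grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    sam_path
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(sam_path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  }
  what <- c("flag", "rname", "pos", "cigar", "mpos", "isize")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  total <- length(flag)
  unmapped      <- bitwAnd(flag, 4L)    != 0L
  reverse       <- !unmapped & bitwAnd(flag, 16L)   != 0L
  secondary     <- !unmapped & !reverse & bitwAnd(flag, 256L)  != 0L
  supplementary <- !unmapped & !reverse & !secondary & bitwAnd(flag, 2048L) != 0L
  keep <- !(unmapped | reverse | secondary | supplementary)
  tallies <- c(total = total, retained = NA_integer_,
               unmapped = sum(unmapped), reverse = sum(reverse),
               secondary = sum(secondary), supplementary = sum(supplementary))

  gene <- as.character(res$rname[keep])
  left <- res$pos[keep] - 1L
  if (paired) {
    proper <- bitwAnd(flag[keep], 2L) != 0L
    first  <- bitwAnd(flag[keep], 64L) != 0L
    fsel <- proper & first
    frag_left <- pmin(left[fsel], res$mpos[keep][fsel] - 1L)
    frag_len  <- abs(res$isize[keep][fsel])
    single <- !proper
    gene <- c(gene[fsel], gene[single])
    left <- c(frag_left, left[single])
    rlen <- c(frag_len,
              GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep][single]))
  } else {
    rlen <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
  }
  tallies["retained"] <- length(gene)

  unknown <- setdiff(unique(gene), names(txome$records))
  if (length(unknown))
    stop("SAM reference names absent from transcriptome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tx_len <- vapply(txome$records, `[[`, 0L, "length")
  bad <- left + rlen > tx_len[gene]
  if (any(bad))
    stop(sprintf("%d alignments extend past their transcript end (first: %s)",
                 sum(bad), gene[which(bad)[1]]), call. = FALSE)

  list(reads = data.frame(gene_id = gene, left = left, read_length = rlen,
                          stringsAsFactors = FALSE),
       tallies = tallies)
}

endmode_name <- function(endmode) {
  if (is.character(endmode)) {
    return(match.arg(endmode, c("5prime", "3prime", "coverage")))
  }
  switch(as.character(as.integer(endmode)),
         "1" = "5prime", "-1" = "3prime", "0" = "coverage",
         stop("endmode must be 1 (5prime), -1 (3prime) or 0 (coverage)",
              call. = FALSE))
}

#' Build a per-transcript occupancy store from alignments
#'
#' Each retained read whose aligned length lies in
#' \code{[smallsize, largesize]} contributes to its transcript's track:
#' \code{5prime} increments the leftmost position, \code{3prime} the
#' rightmost, \code{coverage} every covered position.
#'
#' Scaling follows the convention of the CLI: \code{normalize = -1} divides
#' all tracks by (retained mapped reads / 1e6), i.e. reads-per-million
#' (RPM); \code{normalize = 1e6} leaves raw counts; any other positive value
#' \code{v} divides by \code{v / 1e6} (a user-supplied depth). The RPM
#' denominator is the count of retained (mapped, forward, primary) reads in
#' the whole file, taken before the size window, so size-windowed stores
#' from the same library stay comparable.
#'
#' @param txome A \code{transcriptome}.
#' @param alignments Result of [read_alignments()], or a path to a SAM file.
#' @param normalize \code{-1}, \code{1e6}, or a positive denominator.
#' @param smallsize,largesize Inclusive read-length window (nt).
#' @param endmode \code{1}/\code{"5prime"}, \code{-1}/\code{"3prime"}, or
#'   \code{0}/\code{"coverage"}.
#' @param source_sam Provenance string stored in the result.
#' @return A \code{rocc_store}: per-gene occupancy \code{tracks} (numeric,
#'   one value per transcript nucleotide), the transcript \code{records},
#'   and the build metadata (endmode, size window, normalization, tallies).
#' @export
build_rocc <- function(txome, alignments, normalize = -1,
                       smallsize = 1L, largesize = 1000L,
                       endmode = "5prime", source_sam = "") {
  if (is.character(alignments)) {
    source_sam <- alignments
    alignments <- read_alignments(alignments, txome)
  }
  stopifnot(smallsize <= largesize)
  endmode <- endmode_name(endmode)
  reads <- alignments$reads
  tallies <- alignments$tallies
  retained <- tallies[["retained"]]
  if (retained == 0L)
    warning("no alignments retained; occupancy store is all zero",
            call. = FALSE)

  insize <- reads$read_length >= smallsize & reads$read_length <= largesize
  r <- reads[insize, , drop = FALSE]
  tx_len <- vapply(txome$records, `[[`, 0L, "length")
  tracks <- lapply(tx_len, numeric)

  if (nrow(r)) {
    pos1 <- switch(endmode,
                   "5prime" = r$left + 1L,
                   "3prime" = r$left + r$read_length,
                   "coverage" = NULL)
    if (endmode == "coverage") {
      idx <- split(seq_len(nrow(r)), r$gene_id)
      for (g in names(idx)) {
        sel <- idx[[g]]
        cov <- unlist(Map(seq.int, r$left[sel] + 1L,
                          r$left[sel] + r$read_length[sel]), use.names = FALSE)
        tracks[[g]] <- as.numeric(tabulate(cov, nbins = tx_len[[g]]))
      }
    } else {
      idx <- split(pos1, r$gene_id)
      for (g in names(idx))
        tracks[[g]] <- as.numeric(tabulate(idx[[g]], nbins = tx_len[[g]]))
    }
  }

  if (normalize == -1) {
    denom <- retained
  } else if (normalize == 1e6) {
    denom <- NA_real_  # raw counts
  } else if (normalize > 0) {
    denom <- normalize
  } else stop("normalize must be -1 or a positive number", call. = FALSE)
  units <- "raw"
  if (!is.na(denom) && denom > 0) {
    scale <- 1e6 / denom
    tracks <- lapply(tracks, `*`, scale)
    units <- "rpm"
  }

  structure(list(
    tracks = tracks,
    records = txome$records,
    endmode = endmode,
    smallsize = as.integer(smallsize),
    largesize = as.integer(largesize),
    normalize = normalize,
    denominator = denom,
    total_mapped = retained,
    reads_in_window = nrow(r),
    tallies = tallies,
    units = units,
    source_sam = source_sam
  ), class = "rocc_store")
}

#' @export
print.rocc_store <- function(x, ...) {
  cat(sprintf(
    "<rocc_store> %d transcripts | endmode %s | sizes %d-%d nt | units %s\n",
    length(x$tracks), x$endmode, x$smallsize, x$largesize, x$units))
  cat(sprintf("  reads: %d retained (of %d records), %d in size window\n",
              x$total_mapped, x$tallies[["total"]], x$reads_in_window))
  invisible(x)
}

#' Save / load an occupancy store
#'
#' Lossless, versioned round trip of tracks and all metadata. Loading a file
#' written by an incompatible format version, or a damaged file, is an
#' explicit error.
#'
#' @param rocc A \code{rocc_store}.
#' @param path File path (conventionally \code{.rocc}).
#' @return \code{rocc_save}: \code{path} invisibly. \code{rocc_load}: the
#'   restored \code{rocc_store}.
#' @export
rocc_save <- function(rocc, path) {
  stopifnot(inherits(rocc, "rocc_store"))
  saveRDS(list(format = "riboscope_rocc", version = ROCC_FORMAT_VERSION,
               store = rocc), path)
  invisible(path)
}

#' @rdname rocc_save
#' @export
rocc_load <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read occupancy store '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "riboscope_rocc"))
    stop(sprintf("'%s' is not a riboscope occupancy store", path),
         call. = FALSE)
  if (!identical(obj$version, ROCC_FORMAT_VERSION))
    stop(sprintf("occupancy store '%s' has format version %s; this build reads version %d",
                 path, obj$version, ROCC_FORMAT_VERSION), call. = FALSE)
  obj$store
}

#' Write occupancy tracks as BEDGRAPH
#'
#' Emits 0-based half-open intervals on each transcript's own name, merging
#' adjacent equal-valued positions and omitting zero-valued positions — the
#' layout genome browsers expect for transcriptome-aligned tracks.
#'
#' @param x A \code{rocc_store} (its tracks are written in their stored
#'   units) or a named list of per-gene numeric vectors.
#' @param path Output file.
#' @param scale Multiplier applied to every value before writing; use
#'   \code{1e6 / mapped_count} to put raw 5'-end counts on the RPM scale.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(x, path, scale = 1) {
  tracks <- if (inherits(x, "rocc_store")) x$tracks else x
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(tracks)) {
    v <- tracks[[g]] * scale
    if (!length(v) || all(v == 0)) next
    runs <- rle(v)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths      # 0-based half-open
    nz <- runs$values != 0
    if (any(nz))
      writeLines(sprintf("%s\t%d\t%d\t%s", g, starts[nz], ends[nz],
                         format(runs$values[nz], trim = TRUE,
                                scientific = FALSE, digits = 10)), con)
  }
  invisible(path)
}
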