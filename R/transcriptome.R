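# Region spans are stored 1-based inclusive as integer c(start, end).
# An empty region is encoded start = end + 1 (length 0), which keeps the
# utr5/cds/utr3 tiling arithmetic uniform for transcripts lacking a UTR.

span_len <- function(span) span[2L] - span[1L] + 1L

new_span <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("non-numeric region span", call. = FALSE)
  if (start < 1L || start > end + 1L)
    stop(sprintf("invalid region span %d-%d", start, end), call. = FALSE)
  c(start, end)
}

#' Parse a pipe-delimited transcript header
#'
#' Headers carry transcript metadata in ten pipe-separated fields:
#' gene id, transcript id, protein id, RefSeq NM, RefSeq NP, alias (short
#' gene name), transcript length, and the three region fields prefixed
#' \code{"UTR5:"}, \code{"CDS:"}, \code{"UTR3:"} with 1-based inclusive
#' \code{start-end} coordinates. Both ASCII hyphen and en-dash are accepted
#' as the coordinate separator. The three regions must tile
#' \code{1..length} exactly.
#'
#' @param header_line One header line, with or without the leading \code{">"}.
#' @return A \code{transcript_record} (without sequence): a list with fields
#'   \code{gene_id}, \code{transcript_id}, \code{protein_id}, \code{refseq_nm},
#'   \code{refseq_np}, \code{alias}, \code{length}, and integer spans
#'   \code{utr5}, \code{cds}, \code{utr3}.
#' @examples
#' rec <- parse_header(">G1|T1|P1|N1|NP1|TOY|12|UTR5:1-3|CDS:4-9|UTR3:10-12")
#' rec$length
#' @export
parse_header <- function(header_line) {
  stopifnot(is.character(header_line), length(header_line) == 1L)
  line <- sub("^>", "", trimws(header_line))
  fields <- strsplit(line, "|", fixed = TRUE)[[1]]
  if (length(fields) < 10L)
    stop(sprintf("header has %d '|'-delimited fields; need at least 10: %s",
                 length(fields), line), call. = FALSE)
  n <- length(fields)
  region_fields <- fields[(n - 2L):n]
  prefixes <- c("UTR5:", "CDS:", "UTR3:")
  spans <- vector("list", 3L)
  for (i in 1:3) {
    f <- region_fields[i]
    if (!startsWith(f, prefixes[i]))
      stop(sprintf("field '%s' does not carry prefix '%s'", f, prefixes[i]),
           call. = FALSE)
    body <- sub(prefixes[i], "", f, fixed = TRUE)
    # accept "-" and the en-dash the literature prints
    parts <- strsplit(body, "-|–")[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
      stop(sprintf("non-numeric span in field '%s'", f), call. = FALSE)
    spans[[i]] <- new_span(parts[1], parts[2])
  }
  len <- suppressWarnings(as.integer(fields[7]))
  if (is.na(len))
    stop(sprintf("non-numeric length field '%s'", fields[7]), call. = FALSE)
  rec <- structure(list(
    gene_id       = fields[1],
    transcript_id = fields[2],
    protein_id    = fields[3],
    refseq_nm     = fields[4],
    refseq_np     = fields[5],
    alias         = fields[6],
    length        = len,
    utr5          = spans[[1]],
    cds           = spans[[2]],
    utr3          = spans[[3]],
    sequence      = NULL
  ), class = "transcript_record")
  validate_record(rec, check_sequence = FALSE)
  rec
}

#' Format a transcript record as a header line
#'
#' Inverse of [parse_header()]; always emits ASCII hyphens.
#'
#' @param rec A \code{transcript_record}.
#' @param fasta Prepend \code{">"} when \code{TRUE}.
#' @return A single character string.
#' @export
format_header <- function(rec, fasta = FALSE) {
  s <- sprintf("%s|%s|%s|%s|%s|%s|%d|UTR5:%d-%d|CDS:%d-%d|UTR3:%d-%d",
               rec$gene_id, rec$transcript_id, rec$protein_id, rec$refseq_nm,
               rec$refseq_np, rec$alias, rec$length,
               rec$utr5[1], rec$utr5[2], rec$cds[1], rec$cds[2],
               rec$utr3[1], rec$utr3[2])
  if (fasta) paste0(">", s) else s
}

validate_record <- function(rec, check_sequence = TRUE) {
  id <- rec$gene_id
  if (rec$utr5[1] != 1L)
    stop(sprintf("%s: UTR5 must start at 1", id), call. = FALSE)
  if (rec$utr5[2] + 1L != rec$cds[1] || rec$cds[2] + 1L != rec$utr3[1] ||
      rec$utr3[2] != rec$length)
    stop(sprintf(
      "%s: regions UTR5:%d-%d CDS:%d-%d UTR3:%d-%d do not tile 1..%d",
      id, rec$utr5[1], rec$utr5[2], rec$cds[1], rec$cds[2],
      rec$utr3[1], rec$utr3[2], rec$length), call. = FALSE)
  cl <- span_len(rec$cds)
  if (cl < 3L)
    stop(sprintf("%s: CDS length %d < 3", id, cl), call. = FALSE)
  if (cl %% 3L != 0L)
    warning(sprintf("%s: CDS length %d is not divisible by 3", id, cl),
            call. = FALSE)
  if (check_sequence && !is.null(rec$sequence) &&
      nchar(rec$sequence) != rec$length)
    stop(sprintf("%s: sequence length %d != declared length %d",
                 id, nchar(rec$sequence), rec$length), call. = FALSE)
  invisible(rec)
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s (%s), %d nt; UTR5 %d nt | CDS %d nt | UTR3 %d nt%s\n",
              x$gene_id, x$alias, x$length, span_len(x$utr5), span_len(x$cds),
              span_len(x$utr3),
              if (is.null(x$sequence)) " [no sequence]" else ""))
  invisible(x)
}

new_transcriptome <- function(records, source_label = "") {
  ids <- vapply(records, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(records) <- ids
  structure(list(records = records, source_label = source_label),
            class = "transcriptome")
}

#' Load a reduced transcriptome from FASTA
#'
#' Reads a FASTA file whose record headers follow the pipe-delimited
#' metadata format (see [parse_header()]), attaches the sequences, and
#' cross-checks each declared length against the sequence length.
#'
#' @param fasta_path Path to the FASTA file.
#' @param source_label Free-text provenance attached to the object.
#' @return A \code{transcriptome}: a list with \code{records} (named list of
#'   \code{transcript_record}, keyed by gene id) and \code{source_label}.
#' @export
load_transcriptome <- function(fasta_path, source_label = fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  recs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rec <- parse_header(names(seqs)[i])
    rec$sequence <- toupper(as.character(seqs[[i]]))
    if (nchar(rec$sequence) != rec$length)
      stop(sprintf("%s: sequence length %d != header length %d",
                   rec$gene_id, nchar(rec$sequence), rec$length),
           call. = FALSE)
    recs[[i]] <- rec
  }
  new_transcriptome(recs, source_label)
}

#' @export
print.transcriptome <- function(x, ...) {
  lens <- vapply(x$records, `[[`, 0L, "length")
  cat(sprintf("<transcriptome> %d transcripts, %s nt total%s\n",
              length(x$records), format(sum(as.numeric(lens)), big.mark = ","),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

#' @export
length.transcriptome <- function(x) length(x$records)

# Resolve a user-supplied name (gene id or alias) to a gene id.
resolve_gene <- function(txome, name) {
  if (name %in% names(txome$records)) return(name)
  aliases <- vapply(txome$records, `[[`, "", "alias")
  hit <- names(aliases)[aliases == name]
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L)
    stop(sprintf("alias '%s' is ambiguous (%s)", name,
                 paste(hit, collapse = ", ")), call. = FALSE)
  stop(sprintf("gene '%s' not found in transcriptome", name), call. = FALSE)
}

#' Filter an annotated transcript set down to unique protein-coding models
#'
#' Applies the curation rules used to prepare a reduced transcriptome from a
#' one-isoform-per-gene annotation: non-coding transcripts are removed, and
#' clinical-supplement transcripts (which duplicate gene names and sequences)
#' are removed, leaving protein-coding records with primary "Select" status.
#'
#' @param txome A \code{transcriptome}.
#' @param annotations data.frame with columns \code{gene_id}, \code{biotype}
#'   (\code{"protein_coding"} retained) and \code{status} (\code{"Select"}
#'   retained; e.g. \code{"Plus_Clinical"} removed).
#' @return A filtered \code{transcriptome} with attribute \code{"removed"}:
#'   a named integer vector of counts removed per rule.
#' @export
reduce_annotated_set <- function(txome, annotations) {
  stopifnot(all(c("gene_id", "biotype", "status") %in% names(annotations)))
  ids <- names(txome$records)
  ann <- annotations[match(ids, annotations$gene_id), , drop = FALSE]
  if (anyNA(ann$gene_id))
    stop("annotations missing for: ",
         paste(ids[is.na(ann$gene_id)], collapse = ", "), call. = FALSE)
  noncoding <- ann$biotype != "protein_coding"
  clinical  <- !noncoding & ann$status != "Select"
  keep <- !noncoding & !clinical
  removed <- c(non_coding = sum(noncoding), non_select = sum(clinical))
  if (!any(keep))
    warning("no transcripts retained after annotation filtering", call. = FALSE)
  out <- new_transcriptome(txome$records[keep], txome$source_label)
  attr(out, "removed") <- removed
  out
}

#' Export transcript region annotations as GTF
#'
#' Emits one feature line per non-empty region (\code{5UTR}, \code{CDS},
#' \code{3UTR}) per transcript, with 1-based inclusive coordinates on the
#' transcript's own sequence name and strand \code{"+"} — suitable for
#' loading into a browser alongside transcriptome-aligned tracks.
#'
#' @param txome A \code{transcriptome}.
#' @param path Optional output file; when \code{NULL} the lines are returned.
#' @return Character vector of GTF lines, invisibly when written to file.
#' @export
export_gtf <- function(txome, path = NULL) {
  lines <- character(0)
  feat <- c(utr5 = "5UTR", cds = "CDS", utr3 = "3UTR")
  for (rec in txome$records) {
    for (region in names(feat)) {
      sp <- rec[[region]]
      if (span_len(sp) <= 0L) next
      attrs <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                       rec$gene_id, rec$alias, rec$transcript_id)
      lines <- c(lines, paste(rec$gene_id, "riboscope", feat[[region]],
                              sp[1], sp[2], ".", "+", ".", attrs,
                              sep = "\t"))
    }
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write a transcriptome as FASTA
#'
#' @param txome A \code{transcriptome} whose records carry sequences.
#' @param path Output FASTA path.
#' @param style \code{"longnames"} keeps the full metadata header;
#'   \code{"shortnames"} truncates headers to the gene id (the dialect used
#'   as an alignment reference, so SAM reference names are gene ids).
#' @return \code{path}, invisibly.
#' @export
write_transcriptome_fasta <- function(txome, path,
                                      style = c("longnames", "shortnames")) {
  style <- match.arg(style)
  seqs <- Biostrings::DNAStringSet(vapply(txome$records, `[[`, "", "sequence"))
  names(seqs) <- vapply(txome$records, function(r) {
    if (style == "longnames") format_header(r) else r$gene_id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

# 0-based convenience accessors used throughout internal computation.
cds_start0 <- function(rec) rec$cds[1] - 1L          # first nt of start codon
stop_start0 <- function(rec) rec$cds[2] - 3L          # first nt of stop codon
region_bounds0 <- function(rec, region) {
  sp <- rec[[region]]
  c(sp[1] - 1L, sp[2] - 1L)                           # may be empty (start>end)
}
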