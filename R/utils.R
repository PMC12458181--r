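# Shared helpers: subset lists and RPKM arithmetic.

#' Read a gene subset list
#'
#' Subset files restrict an analysis to transcripts of interest. The file
#' is a CSV/TSV table whose first column is headed \code{genenames} and
#' holds gene ids (ENSG-style).
#'
#' @param path Path to the subset file.
#' @return Character vector of gene names.
#' @export
read_subset <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"genenames" %in% names(df))
    stop(sprintf("subset file '%s' has no 'genenames' column", path),
         call. = FALSE)
  as.character(df$genenames)
}

# Resolve a subset argument (NULL / "none" / character vector / file path)
# to gene ids present in `records`; absent genes warn and are skipped.
resolve_subset <- function(records, subset) {
  if (is.null(subset)) return(names(records))
  if (length(subset) == 1L && (is.na(subset) || subset %in% c("none", "")))
    return(names(records))
  if (length(subset) == 1L && file.exists(subset))
    subset <- read_subset(subset)
  ids <- character(0)
  for (nm in subset) {
    gid <- tryCatch(resolve_gene(list(records = records), nm),
                    error = function(e) NA_character_)
    if (is.na(gid)) {
      warning(sprintf("subset gene '%s' not in transcriptome; skipped", nm),
              call. = FALSE)
    } else ids <- c(ids, gid)
  }
  unique(ids)
}

# Whole-transcript RPKM-style density in store units per kilobase.
gene_rpkm <- function(rocc, gid) {
  sum(rocc$tracks[[gid]]) / (rocc$records[[gid]]$length / 1000)
}

cds_rpkm_of <- function(rocc, gid, shift = 0L) {
  rec <- rocc$records[[gid]]
  tr <- apply_shift(rocc$tracks[[gid]], shift)
  sum(tr[rec$cds[1]:rec$cds[2]]) / (span_len(rec$cds) / 1000)
}
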