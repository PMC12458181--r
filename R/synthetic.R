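# Deterministic toy transcriptomes and footprint simulations with recorded
# ground truth, so every analysis stage has a closed-form recovery test.
#
# The dwell model: within a gene, the probability that a footprint's P site
# sits on a given CDS codon is proportional to that codon's dwell
# multiplier (amino-acid table, with dedicated start/stop multipliers);
# across genes, read counts are proportional to expression. The expected
# pause score of an amino acid therefore equals its dwell multiplier, and
# the expected uORF/CDS per-codon density ratio equals the configured
# translation ratio.

#' Simulation configuration
#'
#' Collects every knob of the toy transcriptome generator and footprint
#' simulator with field-realistic defaults. All randomness is governed by
#' \code{seed}; identical configurations produce identical outputs.
#'
#' @param n_genes Number of transcripts.
#' @param utr5_range,cds_range,utr3_range Length ranges (nt); CDS lengths
#'   are rounded to multiples of 3 and include the stop codon.
#' @param expr_meanlog,expr_sdlog Log-normal per-gene expression.
#' @param mode \code{"80S"} (elongating ribosomes: CDS codon placement) or
#'   \code{"40S"} (scanning subunits: per-nucleotide, frame-independent
#'   placement concentrated in the 5'UTR and on the start codon).
#' @param p_site_offset Distance (nt) from a footprint 5' end to the first
#'   nt of the P-site codon; 12 is typical of 28-nt footprints.
#' @param lengths,length_probs Discrete footprint-length distribution;
#'   defaults peak at 28 nt over 25..34 (80S) — 40S mode defaults to a wide
#'   20..80 distribution peaked near 32 when left \code{NULL}.
#' @param dwell Named per-amino-acid dwell multipliers (unlisted = 1);
#'   e.g. \code{c(P = 3)} makes proline codons threefold slow.
#' @param codon_bias Named codon-usage weights applied when sampling CDS
#'   codons (unlisted codons weight 1); lets specific motifs occur often
#'   enough to study on a small transcriptome.
#' @param start_peak_multiplier Dwell multiplier of the first CDS codon
#'   (initiation peak; gives the start-codon metagene its maximum).
#' @param stop_peak_multiplier Dwell multiplier of the stop codon.
#' @param stop_length_extension Extra nt on stop-codon footprints
#'   (terminating ribosomes protect about 1 nt more).
#' @param uorf_fraction Fraction of genes carrying one planted uORF.
#' @param uorf_translation_ratio,dorf_translation_ratio Per-codon read
#'   density of planted small ORFs relative to the gene's mean CDS codon.
#' @param dorf_fraction Fraction of genes carrying one planted dORF.
#' @param duplicated_segment \code{NULL}, or \code{list(length =, copies =)}
#'   to plant one segment verbatim into several transcripts' 3'UTRs
#'   (multimapping fixture).
#' @param n_reads Footprints to simulate.
#' @param seed Mandatory integer seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 50L,
                       utr5_range = c(60L, 200L),
                       cds_range = c(150L, 600L),
                       utr3_range = c(60L, 200L),
                       expr_meanlog = 1, expr_sdlog = 1,
                       mode = c("80S", "40S"),
                       p_site_offset = 12L,
                       lengths = 25:34,
                       length_probs = NULL,
                       dwell = c(),
                       codon_bias = c(),
                       start_peak_multiplier = 3,
                       stop_peak_multiplier = 2,
                       stop_length_extension = 1L,
                       uorf_fraction = 0,
                       uorf_translation_ratio = 0.5,
                       dorf_fraction = 0,
                       dorf_translation_ratio = 0.1,
                       duplicated_segment = NULL,
                       n_reads = 10000L,
                       seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  if (mode == "40S" && identical(lengths, 25:34)) {
    lengths <- 20:80
    length_probs <- stats::dnorm(lengths, 32, 8)
  }
  if (is.null(length_probs))
    length_probs <- stats::dnorm(lengths, 28, 1.6)
  length_probs <- length_probs / sum(length_probs)
  if (diff(cds_range) < 0 || cds_range[1] < 9L)
    stop("cds_range must allow at least 9 nt (start + one codon + stop)",
         call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), utr5_range = utr5_range,
    cds_range = cds_range, utr3_range = utr3_range,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    mode = mode, p_site_offset = as.integer(p_site_offset),
    lengths = as.integer(lengths), length_probs = length_probs,
    dwell = dwell, codon_bias = codon_bias,
    start_peak_multiplier = start_peak_multiplier,
    stop_peak_multiplier = stop_peak_multiplier,
    stop_length_extension = as.integer(stop_length_extension),
    uorf_fraction = uorf_fraction,
    uorf_translation_ratio = uorf_translation_ratio,
    dorf_fraction = dorf_fraction,
    dorf_translation_ratio = dorf_translation_ratio,
    duplicated_segment = duplicated_segment,
    n_reads = as.integer(n_reads), seed = as.integer(seed)),
    class = "sim_config")
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# n sense codons, optionally excluding ATG (used inside planted small ORFs
# so the planted start is always the last start codon before its stop).
rand_codons <- function(n, no_atg = FALSE, bias = c()) {
  pool <- sense_codons()
  if (no_atg) pool <- setdiff(pool, "ATG")
  w <- rep(1, length(pool))
  hit <- pool %in% names(bias)
  w[hit] <- unname(bias[pool[hit]])
  paste(sample(pool, n, replace = TRUE, prob = w), collapse = "")
}

#' Generate a toy protein-coding transcriptome
#'
#' Builds \code{n_genes} transcripts with random UTRs and a CDS that begins
#' ATG, ends with a stop codon, and contains no internal in-frame stop.
#' Planted features (uORFs, dORFs, duplicated segments) are recorded in a
#' ground-truth table attached as attribute \code{"ground_truth"} (and the
#' per-gene expression levels later used by [simulate_footprints()]).
#'
#' @param config A [sim_config()].
#' @param fasta_path Optional path to also write the longnames FASTA.
#' @return A \code{transcriptome} with attribute \code{"ground_truth"}:
#'   list of data.frames \code{genes}, \code{uorfs}, \code{dorfs},
#'   \code{duplications}.
#' @export
make_toy_transcriptome <- function(config, fasta_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  pick_len <- function(rng, n) sample(seq.int(rng[1], rng[2]), n,
                                      replace = TRUE)
  u5 <- pick_len(config$utr5_range, n)
  cdsl <- pick_len(config$cds_range, n)
  cdsl <- pmax(9L, (cdsl %/% 3L) * 3L)
  u3 <- pick_len(config$utr3_range, n)
  expr <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)

  recs <- vector("list", n)
  uorfs <- list(); dorfs <- list(); dups <- list()
  has_uorf <- stats::runif(n) < config$uorf_fraction
  has_dorf <- stats::runif(n) < config$dorf_fraction

  dup_seg <- NULL
  if (!is.null(config$duplicated_segment)) {
    ds <- config$duplicated_segment
    dup_seg <- rand_nt(ds$length)
  }

  for (i in seq_len(n)) {
    gid <- sprintf("ENSG%08d.1", i)
    utr5 <- rand_nt(u5[i])
    cds <- paste0("ATG", rand_codons(cdsl[i] / 3L - 2L,
                                     bias = config$codon_bias),
                  sample(STOP_CODONS, 1))
    utr3 <- rand_nt(u3[i])

    if (has_uorf[i]) {
      # plant wholly inside the 5'UTR, far enough in for P-site offsets
      aa <- sample(4:10, 1)
      orf_nt <- 3L * (aa + 1L)
      lo <- config$p_site_offset + 3L
      hi <- u5[i] - orf_nt
      if (hi >= lo) {
        s0 <- sample(lo:hi, 1)                       # 0-based start
        orf <- paste0("ATG", rand_codons(aa - 1L, no_atg = TRUE),
                      sample(STOP_CODONS, 1))
        substr(utr5, s0 + 1L, s0 + orf_nt) <- orf
        uorfs[[length(uorfs) + 1L]] <- data.frame(
          gene_id = gid, start_pos = s0, stop_pos = s0 + 3L * aa,
          aa_length = aa, stringsAsFactors = FALSE)
      }
    }
    if (has_dorf[i]) {
      aa <- sample(4:10, 1)
      orf_nt <- 3L * (aa + 1L)
      u3_start0 <- u5[i] + cdsl[i]                   # 0-based utr3 start
      lo <- 3L
      hi <- u3[i] - orf_nt - (max(config$lengths) - config$p_site_offset)
      if (hi >= lo) {
        s_rel <- sample(lo:hi, 1)
        s0 <- u3_start0 + s_rel
        orf <- paste0("ATG", rand_codons(aa - 1L, no_atg = TRUE),
                      sample(STOP_CODONS, 1))
        substr(utr3, s_rel + 1L, s_rel + orf_nt) <- orf
        dorfs[[length(dorfs) + 1L]] <- data.frame(
          gene_id = gid, start_pos = s0, stop_pos = s0 + 3L * aa,
          aa_length = aa, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(dup_seg) && i <= config$duplicated_segment$copies) {
      # verbatim copy planted mid-3'UTR
      ds <- config$duplicated_segment
      if (u3[i] >= ds$length + 10L) {
        s_rel <- 5L
        substr(utr3, s_rel + 1L, s_rel + ds$length) <- dup_seg
        dups[[length(dups) + 1L]] <- data.frame(
          gene_id = gid, start_pos = u5[i] + cdsl[i] + s_rel,
          length = ds$length, stringsAsFactors = FALSE)
      }
    }

    len <- u5[i] + cdsl[i] + u3[i]
    recs[[i]] <- structure(list(
      gene_id = gid,
      transcript_id = sprintf("ENST%08d.1", i),
      protein_id = sprintf("ENSP%08d.1", i),
      refseq_nm = sprintf("NM_%06d.1", i),
      refseq_np = sprintf("NP_%06d.1", i),
      alias = sprintf("TOY%d", i),
      length = len,
      utr5 = c(1L, u5[i]),
      cds = c(u5[i] + 1L, u5[i] + cdsl[i]),
      utr3 = c(u5[i] + cdsl[i] + 1L, len),
      sequence = paste0(utr5, cds, utr3)
    ), class = "transcript_record")
    validate_record(recs[[i]])
  }
  txome <- new_transcriptome(recs, sprintf("synthetic toy (seed %d)",
                                           config$seed))
  empty_orf <- data.frame(gene_id = character(), start_pos = integer(),
                          stop_pos = integer(), aa_length = integer(),
                          stringsAsFactors = FALSE)
  attr(txome, "ground_truth") <- list(
    genes = data.frame(gene_id = names(txome$records), expression = expr,
                       utr5_len = u5, cds_len = cdsl, utr3_len = u3,
                       stringsAsFactors = FALSE),
    uorfs = if (length(uorfs)) do.call(rbind, uorfs) else empty_orf,
    dorfs = if (length(dorfs)) do.call(rbind, dorfs) else empty_orf,
    duplications = if (length(dups)) do.call(rbind, dups) else
      data.frame(gene_id = character(), start_pos = integer(),
                 length = integer(), stringsAsFactors = FALSE))
  if (!is.null(fasta_path)) write_transcriptome_fasta(txome, fasta_path)
  txome
}

aa_of_codons <- function(codons) {
  dna <- Biostrings::DNAStringSet(codons)
  as.character(Biostrings::translate(dna, no.init.codon = TRUE))
}

# Candidate P-site table for 80S mode: one row per (gene, codon) with its
# sampling weight and whether the codon is the stop.
psite_candidates_80s <- function(txome, config, truth) {
  rows <- list()
  maxlen <- max(config$lengths) + config$stop_length_extension
  dwell <- config$dwell
  for (i in seq_along(txome$records)) {
    rec <- txome$records[[i]]
    cs <- cds_start0(rec)
    ncod <- span_len(rec$cds) %/% 3L
    p0 <- cs + 3L * (0:(ncod - 1L))
    codons <- substring(rec$sequence, p0 + 1L, p0 + 3L)
    is_stop <- seq_len(ncod) == ncod
    mult <- rep(1, ncod)
    aa <- character(ncod)
    aa[!is_stop] <- aa_of_codons(codons[!is_stop])
    known <- aa %in% names(dwell)
    mult[known] <- unname(dwell[aa[known]])
    mult[1L] <- config$start_peak_multiplier
    mult[is_stop] <- config$stop_peak_multiplier
    # placement validity for the largest footprint
    ok <- p0 - config$p_site_offset >= 0L &
          p0 - config$p_site_offset + maxlen <= rec$length
    expr <- truth$genes$expression[i]
    base <- expr / ncod
    df <- data.frame(gene_id = rec$gene_id, p0 = p0, weight = base * mult,
                     is_stop = is_stop, stringsAsFactors = FALSE)[ok, ]
    # planted small ORFs: per-codon weight = ratio x mean CDS codon weight
    mean_cds_w <- base * mean(mult)
    add_orf <- function(orfs, ratio) {
      orfs <- orfs[orfs$gene_id == rec$gene_id, , drop = FALSE]
      if (!nrow(orfs)) return(NULL)
      op <- unlist(lapply(seq_len(nrow(orfs)), function(j)
        seq.int(orfs$start_pos[j], orfs$stop_pos[j], by = 3L)))
      ok2 <- op - config$p_site_offset >= 0L &
             op - config$p_site_offset + maxlen <= rec$length
      if (!any(ok2)) return(NULL)
      data.frame(gene_id = rec$gene_id, p0 = op[ok2],
                 weight = ratio * mean_cds_w, is_stop = FALSE,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(
      df,
      add_orf(truth$uorfs, config$uorf_translation_ratio),
      add_orf(truth$dorfs, config$dorf_translation_ratio))
  }
  do.call(rbind, rows)
}

# Candidate per-nucleotide table for 40S mode: scanning density in the
# 5'UTR, a start-codon peak, frame-independent low CDS density.
psite_candidates_40s <- function(txome, config, truth) {
  rows <- list()
  maxlen <- max(config$lengths)
  for (i in seq_along(txome$records)) {
    rec <- txome$records[[i]]
    cs <- cds_start0(rec)
    len <- rec$length
    w <- numeric(len)
    if (span_len(rec$utr5) > 0) w[rec$utr5[1]:rec$utr5[2]] <- 1
    w[rec$cds[1]:rec$cds[2]] <- 0.3
    if (span_len(rec$utr3) > 0) w[rec$utr3[1]:rec$utr3[2]] <- 0.05
    # initiation peak spread over the start codon, frame-neutral
    w[(cs + 1L):(cs + 3L)] <- w[(cs + 1L):(cs + 3L)] + 20 / 3
    p0 <- 0:(len - 1L)
    ok <- p0 - config$p_site_offset >= 0L &
          p0 - config$p_site_offset + maxlen <= len
    expr <- truth$genes$expression[i]
    rows[[i]] <- data.frame(gene_id = rec$gene_id, p0 = p0[ok],
                            weight = expr * w[ok] / len, is_stop = FALSE,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate ribosome footprints and write a SAM file
#'
#' Draws \code{n_reads} footprints from the dwell model described in
#' [sim_config()], assigns each a length from the configured distribution
#' (stop-codon footprints extended by \code{stop_length_extension} nt),
#' places its 5' end \code{p_site_offset} nt upstream of the sampled
#' P-site position, and emits a header-complete SAM of perfect-match,
#' forward-strand, primary alignments.
#'
#' @param txome A \code{transcriptome} from [make_toy_transcriptome()]
#'   (its ground-truth attribute supplies expression levels and planted
#'   ORFs).
#' @param config The same [sim_config()].
#' @param sam_path Optional output path; when \code{NULL} a tempfile is
#'   used.
#' @return List: \code{sam} (path), \code{reads} (data.frame
#'   \code{gene_id}, 0-based \code{left}, \code{read_length},
#'   \code{psite}), \code{candidates} (the sampling frame with weights —
#'   the ground truth for expected densities).
#' @export
simulate_footprints <- function(txome, config, sam_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- attr(txome, "ground_truth")
  if (is.null(truth))
    stop("transcriptome lacks ground truth; build it with make_toy_transcriptome()",
         call. = FALSE)
  set.seed(config$seed + 1L)
  cand <- if (config$mode == "80S")
    psite_candidates_80s(txome, config, truth)
  else psite_candidates_40s(txome, config, truth)

  idx <- sample.int(nrow(cand), config$n_reads, replace = TRUE,
                    prob = cand$weight)
  p0 <- cand$p0[idx]
  gene <- cand$gene_id[idx]
  rlen <- config$lengths[sample.int(length(config$lengths), config$n_reads,
                                    replace = TRUE,
                                    prob = config$length_probs)]
  rlen <- rlen + ifelse(cand$is_stop[idx], config$stop_length_extension, 0L)
  left <- p0 - config$p_site_offset

  if (is.null(sam_path)) sam_path <- tempfile(fileext = ".sam")
  lens <- vapply(txome$records, `[[`, 0L, "length")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  seqs <- vapply(seq_along(idx), function(j)
    substr(txome$records[[gene[j]]]$sequence, left[j] + 1L,
           left[j] + rlen[j]), "")
  recs <- sprintf("read%d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  seq_along(idx), gene, left + 1L, rlen, seqs,
                  strrep("I", rlen))
  writeLines(c(header, recs), sam_path)
  list(sam = sam_path,
       reads = data.frame(gene_id = gene, left = left, read_length = rlen,
                          psite = p0, stringsAsFactors = FALSE),
       candidates = cand, config = config)
}
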