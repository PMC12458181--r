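---
title: "riboscope: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboscope: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscope)
```

This vignette documents how riboscope's computations are defined, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the decisions taken where the design was genuinely open.
It states no empirical result beyond what the package's tests and
acceptance script themselves compute.

## The data model

A *reduced transcriptome* carries one isoform per gene, sense strand only,
with region boundaries encoded in the FASTA header: ten pipe-delimited
fields ending in `UTR5:a-b|CDS:c-d|UTR3:e-f` (1-based inclusive; both `-`
and the typographic en-dash are accepted on input, `-` is emitted). The
three regions must tile `1..length` exactly; a region of zero length is
encoded `start = end + 1` (e.g. `UTR5:1-0`), which keeps the tiling
arithmetic uniform for transcripts lacking a UTR. The CDS is annotated
*including* its stop codon; a CDS length not divisible by 3 is a warning
rather than an error, because real annotations contain such edge cases and
all downstream frame arithmetic uses only the CDS start. Internally every
coordinate is 0-based; 1-based numbers appear only at parse/emit
boundaries (headers, GTF, SAM, output tables).

The first header field (ENSG-style gene id) is the canonical key; the
sixth (the short alias, e.g. a HGNC symbol) is accepted anywhere a gene
name is requested.

## Occupancy stores

`build_rocc` reduces each SAM record to (gene, leftmost position, aligned
length). Records that are unmapped, reverse-strand, secondary, or
supplementary are dropped and tallied — the transcriptome is sense-only,
so antisense alignments are artifacts of the aligner's settings.
Soft-clipped bases are excluded from the read length: end positions must
be alignment-derived. Reads whose aligned length falls inside the
inclusive `[smallsize, largesize]` window increment one position (5'- or
3'-end modes) or every covered position (coverage mode).

Scaling follows the reads-per-million convention: `normalize = -1`
divides by (retained reads / 10^6). The denominator is the retained count
of the *whole file, before the size window*. This choice makes stores
built with different size windows from the same library directly
comparable, and it reproduces the behaviour of the shell idiom
`scalefactor = 1e6 / <mapped read count>` used when preparing browser
tracks. With the window covering all read lengths, the grand total over
all tracks is exactly 10^6 — an identity the acceptance suite asserts.
`normalize = 1e6` keeps raw counts; any other positive value is a
user-supplied denominator.

Paired-end input is supported as an off-by-default option that collapses a
properly-paired pair to one fragment spanning the outer mate coordinates.

## Shifts and reading frames

End-assigned counts are offset to an internal ribosome site before
counting: position `p` moves to `p + shift`, values shifted off the
transcript are discarded and tallied (never wrapped). For 5'-assigned
data from 80S footprints, `shift = 12` typically puts the first
nucleotide of the P site on the anchor; 3'-assigned data use negative
shifts. The reading frame of position `p` is `(p - cds_start) mod 3`,
so adding 3 to a shift never changes any frame assignment — a property
the tests check.

## Small ORFs

uORF/dORF discovery scans the stated UTR for start codons (ATG, or with
`mismatches = 1` also the nine codons at Hamming distance 1) and extends
in frame to the first stop codon, searching past the UTR boundary all the
way to the transcript end; ORFs without a stop are discarded. Among ORFs
sharing a stop, `smallest = 1` keeps the last start, `smallest = 0` the
first. The length threshold is strict (`k` keeps ORFs *longer than* `k`
amino acids; `-k` keeps exactly `k`). Membership is defined by the start
codon lying wholly inside the UTR; the ORF body may overlap the CDS.

In-frame counting sums shifted occupancy at positions congruent to the
start (`(p - start) mod 3 = 0`) from the start codon through the stop
codon's first nucleotide. Including the stop position is deliberate —
terminating ribosomes are real occupancy and stop-codon peaks dominate
real data — and exposed as `include_stop` for users who prefer to exclude
it.

## Metagenes

The start/stop metagene anchors offset 0 at the first nucleotide of the
start (or stop) codon and averages per offset over genes whose transcript
actually covers that offset — a per-offset denominator that avoids edge
artifacts from short UTRs. Two weightings are offered. `weighting = 0`
is the plain arithmetic mean of RPM values, in which highly expressed
genes dominate (the estimator is linear in the tracks). `weighting = 1`
first divides each gene's track by its total CDS occupancy, making every
gene's contribution a "fraction of CDS reads"; genes with zero CDS signal
are excluded, and the estimator is invariant to per-gene rescaling. The
equal weighting is not meaningful for data where the CDS cannot measure
expression (e.g. 40S scanning-subunit profiling).

The gene threshold is a whole-transcript density in store units per
kilobase; `region_size_and_abundance` assigns each read by its raw,
unshifted 5' end (the tool takes no shift parameter) to `start`/`stop`
windows of ±`window` nt around the codon's first nucleotide
(start takes precedence over stop), else to the containing annotated
region. Besides the per-region read-length probability density and read
shares, a length-normalized share weights each read by the reciprocal of
its own gene's region length, so short but dense regions (start, stop)
are visible. The symmetric ±window geometry is this package's documented
convention.

The 3D metagene works directly from SAM (occupancy stores collapse read
length), bins assigned ends by (read length, offset), scales cells to RPM
with the same whole-file denominator rule, and reports the column sums as
the matching conventional profile — an exact identity asserted in tests.

## Metacodon averages and pause scores

`posavg` anchors offset 0 at the first nucleotide of each motif
occurrence; the user supplies the shift that brings the P site onto the
anchor (12 for typical 5'-assigned data). Occurrence windows of
±`bkndwindow` nt are dropped when they run off the transcript (windows
are never padded, keeping denominators comparable) or fall below the
window-density threshold (computed with the window length as the
kilobase denominator). Normalization is either local — each window
divided by its own sum, giving a probability density; zero-sum windows
carry no density and are dropped — or CDS-relative, dividing by the
gene's mean per-nucleotide CDS density computed with a fixed shift of
±13 nt and excluding genes below the CDS-density threshold.

The pause score of an averaged profile is the mean over the three peak
offsets (−1, 0, +1) divided by the mean over the remaining window
positions. The background is thus defined *within the window*; both
components are reported (`peak_mean`, `background_mean`) so the ratio is
auditable. Note a structural consequence: when a motif is frequent, other
occurrences of the same motif fall inside the background of each window
and raise it, so the recovered score for a dwell multiplier *m* is
slightly below *m* even with perfect data. `posstats` scores each
occurrence individually: numerator = mean shifted occupancy over
±`pkwindow` nt, denominator = mean over the rest of the analyzed region
(no window parameter exists for this tool, so the background is
region-wide); occurrences with zero background are dropped and tallied.

Amino-acid motifs are matched against the region translated in the chosen
frame relative to the CDS start (frame 0 is the annotated frame; frames
1/2 shift by +1/+2 nt, which is how internal out-of-frame ORF searches are
expressed). Translation never applies initiator-codon special cases — a
leading TTG is Leu, not Met. `motifs = "all"` enumerates exactly the 20
amino acids or the 61 sense codons.

## Multimapping diagnostics

For exact-match (0-mismatch) questions, an aligner is unnecessary: a
k-mer index over the forward strands answers "how many places can this
read map" deterministically. `generate_fullcov_reads` emits every
possible length-k read; `classify_reads` counts exact sites per read
(every generated read maps at least to its source, hence 100% mapping by
construction); `mm_id_track` writes per-position site counts ≥ 2 (capped
at 100,000) as browser tracks, with 0 marking unique positions. This
replaces a two-pass aligner workflow (unique-only pass, then a
report-up-to-100,000-sites pass on the remainder) in one deterministic
pass. The index can be built in gene-partitioned chunks whose merged
counts are identical to the single pass — counting is associative — which
bounds memory on large transcriptomes. Mismatch-tolerant multimapping
statistics are out of scope: approximate matching at transcriptome scale
is an aligner's job, and the exact-match site count is the metric the
browser tracks encode. Antisense indexing is available as an option for
sensitivity comparisons but is off by default, matching the sense-only
transcriptome.

## The synthetic-data generator

The simulator exists so that every analysis stage has a closed-form
recovery target; its defaults are the package's study conditions and are
not adjusted per test.

The dwell model: a footprint's P site lands on CDS codon *c* of gene *g*
with probability proportional to `expression(g)/n_codons(g) x dwell(c)`.
Dwell multipliers are per amino acid (default 1), with dedicated
multipliers for the first codon (initiation peak, default 3 — without it
a uniform-dwell simulation has no unique start-codon metagene maximum,
since every in-frame offset ties) and the stop codon (default 2, with
stop-codon footprints extended by 1 nt, reflecting the well-documented
longer protection at termination). The 5' end is placed `p_site_offset`
(default 12) nt upstream of the P site; lengths are drawn from a discrete
distribution peaked at 28 nt over 25–34 (80S). Expression is log-normal
(meanlog 1, sdlog 1), a realistic span of ~2 orders of magnitude.
Planted uORFs/dORFs receive per-codon read density equal to
`translation_ratio x` the gene's mean CDS codon density, so the expected
recovered ratio equals the configured value exactly. Planted ORF
interiors exclude in-frame ATGs, guaranteeing the planted start is the
one `smallest = 1` reports. 40S mode places reads per nucleotide
(frame-independent): scanning density across the 5'UTR, a
frame-neutral initiation peak spread over the start codon, low CDS and
3'UTR background, with a wide 20–80 nt length distribution peaked near
32 nt.

Gene structure defaults: 60–200 nt UTRs, 150–600 nt CDS (multiple of 3,
`ATG ... stop`, no internal in-frame stop), uniform codon usage with an
optional `codon_bias` table (used, e.g., to make tri-amino-acid motifs
frequent enough to study on a small transcriptome). Everything is
deterministic given the seed: identical configuration and seed give
byte-identical FASTA and SAM output.

What the simulator does **not** emulate: sequence-dependent nuclease
bias, ligation bias, UMI duplicates, reverse/secondary alignments (an
option injects them only to exercise the ingest filters), partially
degraded frame signal, overlapping transcripts, or genuine biological
codon-usage structure. Recovery tests passing on simulated data therefore
validate the *computations* — coordinate arithmetic, normalization,
weighting, counting — not the biological interpretability of any real
dataset.

## Problem sizes and numerical choices

The test and acceptance suites run at deliberately modest scale: toy
transcriptomes of 10–100 genes (~10–60 kb), simulations of 10^5 reads
for parameter recovery, brute-force oracle comparisons on fixtures under
50 kb. At these sizes the whole suite completes in about a minute and a
half on one core while leaving the statistical recoveries comfortably
inside their tolerances (the pooled uORF ratio at 10^5 reads has a
standard error around 2%, against a ±10% band).

Tolerances and tie-breaks worth knowing: RPM conservation and the 3D
marginal identity are exact (floating-point equality via `all.equal`);
pause-score recovery of a planted multiplier of 3 is checked within ±15%,
which absorbs the background-inflation effect described above; 40S frame
shares are checked within ±3 percentage points of 1/3. Ties in
`which.max` resolve to the first offset, which is unambiguous in practice
because the initiation peak is strict. Degenerate inputs are defined
rather than accidental: empty alignment sets build all-zero stores with a
warning; empty regions produce RPKM 0 with a flag; occurrences whose
windows truncate are dropped; zero-background pause occurrences are
dropped and tallied.

## Container format

The occupancy store serializes via R's RDS with an embedded format-version
field checked on load; truncated or foreign files fail with explicit
errors. Version 1 stores full per-gene numeric tracks; a future version
could store per-read-length layers at the cost of size.

## Command-line interface

Each analysis is also exposed as a positional-argument subcommand
(`builddense`, `writegene2`, `genelist`, `smorflist`, `metagene`,
`posavg`, `posstats`, `region_size_and_abundance`, `metagene_3d`,
`fullcov`, `mmid`, `mmstats`, `simulate`) through `riboscope::main()` /
`dispatch()` and the `inst/cli/riboscope` script. Every run echoes its
parsed parameters and read tallies as machine-parseable `## key value`
lines on standard output before writing CSV results, so analyses are
self-documenting. Subset lists are CSV/TSV files whose first column is
headed `genenames`.

## Known limitations

- One isoform per gene by construction; no genome-coordinate conversion,
  no splice-aware analysis.
- Exact-match multimapping only; mismatch-tolerant statistics require an
  external aligner.
- The ROCC store collapses read length (the 3D metagene works from SAM
  for this reason).
- No statistical thresholding/FDR for calling smORFs "expressed" — the
  in-frame counts are inputs to whatever thresholding a study needs.
- BIGWIG export is not implemented; BEDGRAPH output converts readily with
  standard tools.
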