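Package: riboscope
Title: Transcriptome-Centric Ribosome Profiling Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis suite for ribosome profiling (Ribo-seq) and related
    short-read data aligned to a reduced, splice-free transcriptome. Converts
    transcriptome-aligned SAM files into per-transcript occupancy stores with
    5'-end, 3'-end, or coverage assignment and reads-per-million scaling, and
    derives per-gene position tracks, region and reading-frame quantitation,
    upstream/downstream open reading frame discovery with near-cognate starts
    and in-frame read counting, start/stop metagenes with gene-equal weighting,
    read-length-resolved (3D) metagenes, metacodon averaging with pause scores,
    and exact-match multimapping diagnostics. Includes a deterministic
    synthetic footprint simulator with known ground truth for parameter
    recovery testing, plus BEDGRAPH and GTF export for genome browsers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    graphics,
    grDevices,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
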