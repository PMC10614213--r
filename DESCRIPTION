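Package: xrseq
Title: Simulation and Analysis of Excision-Repair Sequencing (XR-seq) Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates UV excision-product sequencing (XR-seq) libraries from
    plasmid-scale references with known ground truth (excised-oligomer length
    distributions, dipyrimidine damage sites, unique molecular identifiers,
    adapters, PCR duplicates, strand-asymmetric transcription-coupled repair),
    and processes such libraries through deduplication, adapter/UMI trimming,
    exact-match alignment, damage-position filtering, and subsampling into
    strand-resolved repair maps, length and positional nucleotide profiles,
    and per-gene transcribed/nontranscribed strand (TS/NTS) repair ratios,
    including the TCR ratio-of-ratios between repair-coupling-factor
    proficient and deficient libraries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'xrseq-package.R'
    'utils.R'
    'reference-io.R'
    'simulate.R'
    'preprocess.R'
    'align.R'
    'repair-map.R'
    'tcr.R'
    'pipeline.R'
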