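Package: guidecraft
Title: CRISPR/Cas9 sgRNA Target Site Discovery, Off-Target Search and Ranking
Version: 0.1.0
Authors@R:
    person("Guidecraft", "Developers", email = "guidecraft@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate single-guide RNA (sgRNA) target sites in a
    query DNA sequence, enumerates genome-wide potential off-target sites
    under a seed-constrained mismatch model with PAM (protospacer adjacent
    motif) constraints, annotates off-targets with the nearest exon,
    scores and ranks candidates by off-target quality and exon proximity,
    and emits cloning oligonucleotide pairs plus FASTA/TSV/BED reports.
    Includes a deterministic synthetic-genome generator that plants target
    and off-target sites with specified mismatch configurations so the
    whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
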