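Package: centerscan
Title: Motif-Based Discovery of Hidden Functional Centers in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers hidden functional centers (catalytic, gas-sensing and
    hormone-binding sites) embedded in complex multi-domain proteins. Builds
    consensus search motifs from alignments of annotated centers, scans
    proteome FASTA files with PROSITE-dialect patterns supporting residue
    classes, exclusions and ranged wildcard gaps (including five curated
    motifs for guanylate/adenylate cyclase, phosphodiesterase, H-NOX
    gas-sensing and abscisic-acid-interacting centers), annotates
    cyclase hits for a downstream acidic cation-binding variant, ranks
    candidates by physicochemical similarity (molecular weight, isoelectric
    point, hydrophobicity) to experimentally validated reference centers,
    and exports ranked candidates as TSV, GFF3 and FASTA for downstream
    structural assessment. A deterministic synthetic-proteome generator with
    planted motif instances supports benchmarking without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
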