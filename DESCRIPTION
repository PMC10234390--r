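Package: sirtail
Title: Discovery of siRNA Regions and 3' Nontemplated Tails from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers small interfering RNAs (siRNAs) in small RNA-seq
    alignments as clusters of reads mapping antisense to user-chosen
    annotated genomic features, and quantifies 3' nontemplated nucleotide
    tails on siRNAs or any predefined small-RNA regions. Candidate regions
    are built by merging same-strand annotation features and excising bases
    covered on both strands; antisense read blocks are clustered into
    putative siRNA regions gated by minimum read support and span; tails are
    re-derived as the maximal zero-mismatch templated genomic prefix of each
    read. Includes counts-per-million quantification with read-abundance
    filtering, a fully deterministic synthetic-fixture generator (toy
    genome, annotation, reads with planted antisense clusters and known
    tails), and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
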