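Package: medipr
Title: MeDIP-Seq Methylome Analysis with Synthetic Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for genome-wide DNA methylation analysis
    from MeDIP-seq (methylated DNA immunoprecipitation sequencing) data:
    CpG-island detection by the Gardiner-Garden criteria, highly methylated
    region (HMR) calling with a Poisson window model, genomic-feature
    annotation of peaks and islands, metagene TSS/gene-body/TTS methylation
    profiles, promoter-methylation versus expression-decile correlation,
    resampled Fisher's-exact GO enrichment, and per-CpG bisulfite-clone
    methylation calls. A first-class synthetic-data module generates a toy
    genome with a planted methylation landscape, simulated MeDIP tags, RNA
    tag counts and bisulfite clones, so the whole pipeline can be exercised
    and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
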