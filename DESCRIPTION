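Package: primarytx
Title: Primary-Transcriptome Genome Reannotation for High-GC Bacteria
Version: 0.1.0
Authors@R:
    person("Genome", "Annotation Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reannotating bacterial genomes from 5'-enriched and
    whole-transcriptome RNA-seq profiles. Calls transcription start sites
    (TSS) from per-base 5'-read-start stacks, classifies them by genomic
    context (primary, secondary, antisense, intragenic, intergenic),
    analyzes 5'-UTR lengths and leaderless transcription, proposes
    translation-start corrections from intragenic TSS, discovers -10/-35
    promoter and ribosome-binding-site motifs with a ZOOPS EM search and
    spacer statistics, infers operons and sub-operons from intergenic
    bridging reads, and detects transcription-attenuator leader peptides
    with Rho-independent terminator signatures. Ships a synthetic-genome
    generator with planted ground truth so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
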