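Package: estsplice
Title: Alternative Splicing Event Detection from Spliced EST Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies alternative splicing events (intron
    retention, exon skipping, alternative 5'/3' splice sites, and events
    altering both intron boundaries) from spliced EST/cDNA-to-genome
    alignments in BLAT PSL format. Alignments are quality-filtered,
    clustered into transcriptional units, and summarized as splice graphs;
    classified events are scored for splice-site strength with log-odds
    position weight matrices trained on constitutive introns, contrasted
    for intron/exon length and GC content, and assessed for their impact
    on predicted ORFs including premature termination codons and
    nonsense-mediated decay candidacy under the 50-nt rule. A synthetic
    genome and EST simulator with planted events of known truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    igraph,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
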