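Package: riboTE
Title: Feature-Resolved Translation Efficiency and Polysome Profiling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for translational profiling of transcriptional
    reprogramming events such as a DUX4 pulse: derivation of the five mRNA
    features (5'UTR, translation initiation site window, first coding exon,
    CDS, 3'UTR) from transcript annotation, P-site assignment and
    feature-level counting of ribosome-protected fragments, a native
    negative-binomial interaction test for differential translation
    efficiency between Ribo-seq and RNA-seq, spike-in normalized
    differential polysome association in three formulations, 5'UTR minimum
    free energy structure comparison, and a fully deterministic synthetic
    study generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
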