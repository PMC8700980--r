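Package: regcascade
Title: Regulatory Cascade Analysis of Neurodevelopmental Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for inferring transcription-factor regulatory
    cascades from developmental RNA-seq count data. Implements expression
    filtering and a calibrated negative-binomial Wald test for differential
    expression, per-sample pathway activity scoring by a rank random-walk
    statistic, JASPAR motif parsing with exact p-value score thresholds for
    promoter scanning, lncRNA target inference by enhancer interval overlap,
    correlation-gated regulatory network activation, and rooted cascade growth
    with disease-versus-control comparison. Ships a synthetic study generator
    (genome, annotations, motifs, reference network, negative-binomial counts
    with planted regulatory structure) so every stage is testable against
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
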