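Package: venomgland454
Title: Venom-Gland 454 Transcriptome Annotation and Toxin Gene-Copy Estimation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed 454-style venom-gland transcriptome
    reads: MID demultiplexing, microsatellite/low-complexity masking, toxin-family
    annotation by exhaustive translated and nucleotide local alignment against a
    bundled reference panel with Karlin-Altschul E-values, estimation of the minimum
    number of gene copies per toxin family from error-rate-aware read clustering,
    coverage-thresholded amino-acid consensus calling, family-abundance quantitation
    (reads% and mol%) with transcriptome-proteome comparison and PCA, and a
    distance-based cladogram from concatenated consensus sequences. Includes a
    ground-truth read simulator emulating 3'-enriched pyrosequencing libraries so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
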