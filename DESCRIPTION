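Package: chillsem
Title: Chilling-Responsive Gene Screening and PLS Path Modeling of Gene Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens chilling-responsive genes from small multi-timepoint
    RNA-seq designs using a transparent negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg false discovery
    rate control, partitions them into hormone-, transcription-factor- and
    antioxidant-related blocks, and quantifies direct and mediated
    relationships among the blocks with partial least squares structural
    equation modeling (Lohmoeller iteration, path weighting scheme,
    bootstrap inference with individual sign correction, AVE and composite
    reliability diagnostics, exact direct/indirect effect decomposition on
    DAGs). Ships a synthetic-data generator with known negative-binomial
    differential-expression structure and known latent path structure so
    the whole pipeline is verifiable without external data, plus qRT-PCR
    relative quantification (2^-ddCt) and RNA-seq/qPCR concordance
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
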