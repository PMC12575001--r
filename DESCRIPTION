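Package: spliceml
Title: Splice-Site Prediction with Dilated Residual Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A trainable splice-site prediction toolkit. Converts genome FASTA
    and GFF3/GTF annotation into supervised per-nucleotide splice-site datasets,
    builds and trains dilated residual convolutional network models at four
    context sizes, calibrates output probabilities by class-wise temperature
    scaling, runs windowed ensemble prediction to BED, annotates VCF variants
    with splice delta scores, and computes in-silico mutagenesis importance
    profiles. Includes a seeded synthetic-genome generator with planted
    multi-exon genes so the full pipeline is testable on toy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
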