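Package: miRTarPC
Title: miRNA Target Prediction from Matched mRNA, Protein and miRNA
    Profiles via Conditioned Partial Correlation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts microRNA-target interactions from matched
    multi-omic expression data (mRNA, protein and miRNA matrices over
    the same samples). For every gene/miRNA pair the package contrasts
    the bivariate Pearson correlation between a gene's mRNA and protein
    levels with the partial correlation conditioned on the miRNA: pairs
    whose conditioned correlation becomes markedly more significant are
    called candidate targets (top quartile of positive p-value
    improvements). Includes the published preprocessing recipe
    (missingness filtering, median imputation, log2 transform,
    top-variance protein selection), hypergeometric enrichment against
    known target-pair databases with two bivariate-correlation
    baselines, seed-match annotation of candidates against a genome
    FASTA/GTF (seed = bases 2-8 from the miRNA 5' end, longest
    transcript per gene), a chromosomally ordered results heatmap, and
    a synthetic-data generator with planted miRNA-mediated repression
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
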