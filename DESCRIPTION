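Package: saluki
Title: Consensus mRNA Half-Life Estimation and Sequence-Based Stability Modeling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of transcriptome-wide mRNA decay-rate
    measurements and for predicting mRNA half-life from sequence. Harmonizes
    heterogeneous half-life datasets (log transformation, gene filtering,
    per-sample standardization, EM-based iterative PCA imputation, quantile
    normalization) into consensus per-gene half-lives taken as the first
    principal component of the processed gene-by-sample matrix, and
    quantifies method bias and cell-type specificity. Builds representative
    transcript models from GTF/FASTA annotations, extracts sequence and
    biochemical feature groups (basic mRNA properties, codon and k-mer
    frequencies, windowed binding scores, CLIP peak counts), and fits
    L1-regularized linear models with nested feature-group comparisons.
    Implements Saluki, a hybrid convolutional and recurrent neural network
    that predicts half-life from a 6-track encoding of the spliced mRNA
    (nucleotides, exon junctions, codon frame), trained jointly on two
    species with a shared trunk, together with an interpretation toolkit:
    in-silico saturation mutagenesis, metagene aggregation, motif and codon
    insertional scans, variant and reporter-construct effect scoring, and
    matched variant-set benchmarking. Includes seeded generators for
    synthetic transcriptomes and multi-study half-life compendia with
    planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    limma,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Regression, Sequencing
RoxygenNote: 7.3.3
LinkingTo: Rcpp
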