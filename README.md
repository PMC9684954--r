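# saluki

Consensus mRNA half-life estimation and sequence-based stability
modeling for mammalian transcriptomes.

## The problem

Transcriptome-wide mRNA decay measurements disagree between studies:
the two experimental families — metabolic pulse labeling (4sU, BrU,
5EU) and transcriptional shutoff (ActD, alpha-amanitin) — carry
systematic, opposite biases, and per-study batch effects often exceed
any cell-type signal. This package implements the full chain from a
noisy multi-study compendium to a predictive sequence model:

1. **Compendium harmonization** — a sparse gene x sample matrix is
   log-transformed with unit-aware pseudocounts, filtered by
   measurement support, z-scored per sample, completed by EM iterative
   PCA imputation (rank chosen by cross-validated imputation error),
   and quantile normalized. The first principal component of the
   processed matrix (samples as variables, sign-anchored to per-gene
   means) is the consensus half-life phenotype; rank-sum diagnostics
   quantify method-class bias and cell-type specificity.
2. **Feature models** — per-gene feature groups (basic mRNA
   properties; 61 codon frequencies; 21,844 k-mer frequencies per
   region; windowed RBP-binding scores; strand-aware CLIP peak counts;
   external score tables) feed L1-regularized regression with fixed
   10-fold splits, nested model comparison by one-sided paired t-tests
   with Bonferroni correction, and coefficient/collinearity reports.
3. **Saluki** — a hybrid convolutional/recurrent network predicting
   half-life from an `L x 6` encoding of the spliced mRNA (one-hot
   nucleotides, exon-junction track, codon-frame track): seven
   convolution+max-pool stages down to 128-nt resolution, a GRU
   running backward from the padded 3' end, and species-specific
   output heads on a shared trunk — 155,521 trainable parameters per
   species at the published 64-channel configuration. An
   interrogation toolkit provides in-silico saturation mutagenesis,
   metagene aggregation, motif/codon/splice-site insertional scans,
   variant and reporter-construct scoring, and a matched fine-mapped
   variant benchmark (midrank AUROC).

Seeded generators for synthetic transcriptomes (with planted junction,
codon and 3'UTR-motif effects and an exact effect ledger) and
multi-study compendia (batch structure, method-class bias, monotone
distortions, missingness, mixed units) make every step testable
without downloads.

## Worked example

```r
library(saluki)

## a synthetic compendium with known ground truth
spec <- generativeSpec(n_genes = 500)
tx   <- genTranscriptome(spec, seed = 1)
lat  <- genLatentHalflives(tx$ts, spec, seed = 2)
cmp  <- genCompendiumMatrix(lat$latent, compendiumSpec(), seed = 3)

res <- runConsensusPipeline(cmp$values, cmp$meta,
                            min_samples = 10, ncp_max = 5, seed = 4)
res$ncp
#> [1] 2
varianceExplained(res$consensus)[1]
#> [1] 0.5792676
cor(geneScores(res$consensus), lat$latent[names(geneScores(res$consensus))])
#> [1] 0.8787972
```

At this small demonstration size (500 genes, 20 samples, 30% missing,
per-sample noise sd 0.5 plus batch and method-class effects) the
consensus PC1 explains 58% of variance and recovers the planted latent
half-life at r = 0.88; at the standard validation size (2000 genes)
the recovery exceeds 0.95. On top of the consensus:

```r
## feature-based model of the consensus
ft <- buildFeatureTable(tx$ts, c("B", "C"))
folds <- assignHomologyFolds(geneIds(tx$ts), character(0), seed = 5)$human
fit <- fitLassoCV(ft, res$consensus, folds, code = "BC", seed = 6)
round(mean(fit$fold_r), 2)
#> [1] 0.64
```

The basic + codon feature model explains the consensus at a mean
held-out correlation of 0.64 — the planted determinants (junction
density, codon usage) are being read back out of the harmonized
measurement.

and the network, at a scaled-down configuration:

```r
enc <- encodeTranscripts(tx$ts, L_max = 1024, species = "human")
model <- trainSaluki(enc, lat$latent, list(human = folds), test_fold = 1,
                     hyper = salukiHyperparams(L_max = 1024, channels = 32,
                                               heads = "human"),
                     seed = 7, max_epochs = 20)
```

`salukiParamCount(buildSaluki(salukiHyperparams()))` returns `155521`,
the trainable-parameter count of the full-scale model.

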