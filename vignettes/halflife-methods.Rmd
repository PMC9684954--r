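---
title: "Consensus mRNA half-lives and sequence-based stability models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus mRNA half-lives and sequence-based stability models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saluki)
```

# The scientific problem

Transcriptome-wide mRNA half-life measurements disagree substantially
between laboratories, cell types and, most systematically, between the
two experimental strategies available: metabolic pulse labeling (4sU,
BrU, 5EU) and transcriptional shutoff (actinomycin D, alpha-amanitin).
This package implements, end to end, the machinery needed to (i) distill
a heterogeneous compendium of such datasets into a consensus per-gene
half-life phenotype, (ii) model that phenotype from interpretable
sequence and biochemical features with L1-regularized regression, and
(iii) train and interrogate Saluki, a hybrid convolutional/recurrent
neural network that predicts half-life directly from a 6-track encoding
of the spliced mRNA.

# Harmonizing a half-life compendium

The pipeline in `runConsensusPipeline()` is a fixed sequence of
stage-tagged transformations of a sparse gene x sample matrix
(`HalfLifeMatrix`, a `SummarizedExperiment` whose column data carry the
study, species, cell type, method, method class, unit and
degradation-rate flag of every sample):

1. **Transform** (`preprocessHalflives`): `log10(x + 0.1)` for samples
   in hours, `log10(x + 1)` for minutes — the pseudocount is on the
   measurement scale, so 0.9 h maps exactly to 0. Samples deposited as
   degradation rates are transformed the same way and negated, making
   "larger = longer-lived" universal. Duplicate gene IDs are averaged
   after the transform.
2. **Filter** (`filterGenes`): keep genes with enough non-missing
   samples (10 for the human compendium, 5 for mouse).
3. **Standardize** (`standardizeSamples`): z-score each sample's
   observed values (n-1 denominator). Together with the later quantile
   normalization this makes the log base immaterial; a test asserts
   the invariance.
4. **Impute** (`imputeIterativePCA`): EM-style iterative PCA. Missing
   cells start at column means and are repeatedly overwritten by a
   rank-`ncp` SVD reconstruction of the completed, column-centered
   matrix until the largest change on an imputed cell falls below 1e-6
   (at most 1000 iterations; non-convergence is an error). Observed
   cells are never touched. The rank is chosen by K-fold (default 5)
   cross-validation: additional observed cells are masked, each
   candidate rank in `0..ncp_max` re-imputes them, and the rank with
   the smallest masked-cell MSE wins. Because plain EM-PCA converges
   arbitrarily slowly at noisy high ranks (tiny eigengaps), the CV
   scoring runs are capped at 300 iterations with tolerance 1e-4 —
   an adequate score for ranking ranks; the final imputation keeps the
   strict contract. A generalized-CV approximation is available as
   `method = "gcv"`.
5. **Quantile-normalize** (`quantileNormalize`, via
   `limma::normalizeQuantiles`): every column receives the identical
   sorted value vector (the across-sample mean of order statistics);
   ties get the average of the tied quantiles. Alternate tie rules
   would change only tied entries.
6. **Consensus** (`consensusPC1`): PCA with samples as variables
   (column-centered, unscaled). PC1 scores are the consensus,
   cell-type-agnostic half-life phenotype. The eigenvector sign is
   arbitrary, and some source datasets are deposited as rates, so the
   orientation is anchored: scores must correlate positively with the
   per-gene mean of the processed matrix. (Note that this anchor is
   relative to the matrix at hand: globally negating the input flips
   the row means and hence the anchored scores — the anchor
   canonicalizes the eigenvector sign, not the data sign.)

Two diagnostics quantify the bias structure. `samplePCA()` runs PCA on
the transposed matrix; `methodBiasTest()` averages PC2 within (study,
method class) so replicate-heavy studies count once, then compares
pulse-labeling and shutoff studies with a two-sided rank-sum test.
`celltypeSpecificityTest()` computes Pearson correlations of every
cross-study sample pair (same-study pairs would inflate agreement),
splits them into same/different cell type, and applies a one-sided
rank-sum test. Both tests use exact enumeration over rank assignments
whenever the group sizes permit (at most ~200,000 assignments), which
handles ties exactly — fully separated 3-vs-3 groups give the exact
two-sided p of 2/20 = 0.1. Whether the correlations are computed on
imputed values or on pairwise-complete (pre-imputation) observations is
exposed as `genes = c("all", "common")`, since both variants are
informative and the headline choice is not derivable from first
principles.

# Feature extraction

`readTranscriptSet()` builds one representative transcript per
protein-coding gene from a GTF and FASTA: the transcript with the
longest ORF, then the longest 5'UTR, then the longest 3'UTR; residual
ties go to the lexicographically smallest transcript ID for
reproducibility. Internal coordinates are 0-based half-open on the
spliced sequence, always 5'-to-3' in mRNA sense (minus-strand genes are
reverse-complemented at ingestion); T is normalized to U and ambiguity
codes other than N are rejected.

Feature groups carry single-letter labels used to assemble model codes
such as `"BC3MS"`:

* **B** — 8 basic properties: G/C content of the three regions,
  `log10(x + 0.1)`-transformed region and intron lengths, and ORF
  exon-junction density (junctions strictly inside the ORF per kb of
  ORF).
* **C** — 61 codon frequencies: non-overlapping codons, normalized by
  the total codon count including stops (codons containing N drop out
  of numerator and denominator), stop codons removed from the output.
* **5 / O / 3** — overlapping k-mer frequencies, k = 1..7, per region;
  each k is normalized separately so it forms a proper distribution,
  giving 4 + 16 + ... + 16384 = 21,844 features per region.
* **M, S, D, R** — external per-gene scores attached through
  `ingestScoreTable()` (microRNA context scores are negated so larger
  means more repression) or through the windowed-averaging harness
  `windowAverageScores()`, which tiles a region in 50-nt windows,
  pads each window with neighboring transcript sequence (or N at
  transcript boundaries) to 1000 nt (flank 475) or 150 nt (flank 50),
  and divides the per-factor score sums by the region length.
* **E, e, m, P** — strand-aware CLIP peak counts per gene body
  (`peakCountFeatures()`, >= 1 bp overlap), transformed
  `log10(x + 1)`.

Missing cells in externally-derived feature columns are filled by
`imputeFeatureMissing()`: a linear predictor on the complete basic
features, fitted per column on its observed rows. With complete
anchor predictors of full rank this least-squares imputation coincides
with the partial-least-squares flavor used in comparable pipelines.

# Lasso modeling

`fitLassoCV()` z-scores features and target globally by default — the
reproduction choice; `standardize = "fold"` estimates scaling on each
training portion instead, which is the leakage-free variant and
generally differs slightly. For each outer fold the penalty is selected
by inner 10-fold CV on the training portion over a 100-value
log-spaced grid spanning four orders of magnitude below the smallest
empty-support penalty (the glmnet default grid), with the
minimum-mean-MSE rule (`lambda_rule = "1se"` optional). Pairs of nested
model codes are compared with one-sided paired t-tests on the 10
held-out per-fold correlations, Bonferroni-corrected over the declared
number of comparisons. Degenerate cases follow fixed conventions:
identical per-fold correlations give p = 1; constant nonzero
improvements give p = 0; constant held-out predictions give r = 0 with
a flag. `interpretModel()` refits on all data at a CV-chosen penalty
and reports the top-30 coefficient magnitudes along with every feature
correlated at |r| >= 0.8 with a top feature — the honest unit of
interpretation under lasso's arbitrary choices among collinear columns
(coordinate descent may even split weight across exact duplicates).

# The sequence model

`encodeMrna()` produces an `L_max x 6` tensor: one-hot A/C/G/U (N is
all-zero), a splice track marking the 5'-most nucleotide of every
non-first exon, and a codon track marking the first nucleotide of every
codon (which implicitly delimits the UTRs). mRNAs longer than `L_max`
keep their 3'-most window — regulatory density concentrates toward the
3' end — and shorter ones are zero-padded at the 3' end.

The network (`buildSaluki()`) is an initial width-5 convolution over
the 6 input tracks followed by max pooling, then six blocks of [layer
norm, ReLU, width-5 convolution, dropout, max pooling] — seven pooling
steps in total, so a 12,288-nt input reaches 128-nt resolution — then
layer norm, ReLU and a GRU that runs backward from the padded 3' end so
its final hidden state sits at the information-dense 5' end; a shared
dense block (batch norm, ReLU, bias-free dense — the following batch
norm absorbs any bias) and one output head per species (batch norm,
ReLU, dense to 1). Layer normalization is used inside the tower because
the 3' zero padding would corrupt batch statistics; batch normalization
is safe at the vector stage. At the published full-scale configuration
(64 channels) the parameter count of one forward path — shared trunk
plus one species head — is exactly 155,521; this simultaneously pins
down the block-count reading (an initial convolution plus six further
blocks) and the dense widths, since no standard two-head variant can
produce an odd total. Numerical choices: layer-norm epsilon 1e-3
(padded positions are constant vectors whose normalization gradient
would explode at smaller epsilon), batch-norm epsilon 1e-3 and
momentum 0.9, He-normal convolution initialization, Glorot-uniform GRU
input kernels, orthogonal recurrent kernels, two GRU bias vectors (the
gate-after-bias convention), max-pool ties resolved to the earlier
position.

Training (`trainSaluki()`) minimizes MSE with Adam (learning rate
1e-3, beta1 0.9, beta2 0.98, epsilon 1e-7), global-norm gradient
clipping at 0.5, L2 1e-3 on convolution, GRU and dense weights, and
dropout 0.3. Human and mouse batches alternate strictly, updating the
shared trunk plus the respective head; an epoch ends when the larger
species is exhausted and the smaller is recycled. Targets are z-scored
within species; predictions are in z-units. One fold is held out as
test and never seen, a second as validation; after every epoch the
validation Pearson correlation (averaged over species) is recorded and
the parameters of the best epoch are restored at the end
(early-stopping patience 25 epochs). During training each presentation
of a sequence is stochastically shifted by up to +/-3 nt with zero
fill (`augment_shift`), which discourages memorization of absolute
positions; inference is always unshifted. One master seed fans out to
weight initialization, batch order and dropout, so identical seeds
give identical trained models. The heavy kernels (convolution via
BLAS-backed tap GEMMs, fused layer-norm/ReLU, pooling, dropout) are
implemented in C++; their gradients are verified against plain-R
reference layers and finite differences in the test suite.

`trainSalukiEnsemble()` trains the fold x replicate grid;
`ensemblePredict()` averages the replicates of a gene's own test fold
(`mode = "heldout"`, the honest cross-validated prediction) or all
members (`mode = "external"`, for third-party sequences).

# Interrogating a trained model

All effects are reported as Delta = alt - ref: negative means
destabilizing.

* `ism()` — in-silico saturation mutagenesis: three forward passes per
  position. Auxiliary tracks are held fixed even for stop-gain
  mutations, so effects isolate the nucleotide change; this avoids the
  disproportionate predictions that recoding the frame track after a
  premature stop would create.
* `ismMetagene()` — positions are mapped to percentile bins within
  their functional region, |mean effect| is averaged within
  (half-life quartile, region, bin).
* `insertMotifScan()` / `insertCodonScan()` / `insertSpliceSiteScan()`
  — an element is written over the reference at the anchor of each of
  50 evenly divided bins per region (length-preserving replacement;
  partial fits at region ends are skipped; codons snap to the first
  in-frame start within the bin and never overwrite the stop codon;
  splice-site insertion sets a single splice-track bit). Valid mRNAs
  have 5'UTR >= 100 nt, ORF >= 500 nt, 3'UTR >= 500 nt. Deltas are
  averaged per bin across mRNAs; the per-codon mean over ORF bins is
  the quantity comparable to codon stability coefficients.
* `variantEffect()` — per-variant Delta with reference-allele
  verification; `smoothTrack()` provides the 8-nt centered moving
  average (window shrinking at the edges) used for display tracks.
* `reporterEffect()` — splices a fragment into a reporter scaffold's
  3'UTR and predicts the chimera; the default scaffold is synthetic
  (`syntheticReporterScaffold()`) because real vector sequences are
  proprietary inputs.
* `matchedVariantBenchmark()` — positives are fine-mapped variants
  with PIP > 0.9; each is matched without replacement to a PIP < 0.01
  variant from the same transcript region, a different gene, and the
  closest gene expression; AUROC of the |Delta| ranking uses the
  midrank convention, which equals exhaustive pair enumeration.

# The synthetic-data generators

`genTranscriptome()` and `genCompendiumMatrix()` define the package's
study conditions; they are pure functions of (spec, seed).

The transcriptome generator draws region lengths log-normally (5'UTR
median 100 nt, ORF median 150 codons, 3'UTR median 300 nt — a
deliberately compact transcriptome whose mRNAs, median ~850 nt, fit
the scaled-down 1024-nt encoder), exon counts as 1 + Poisson(4) with
junctions uniform over the spliced length, and uniform-composition
UTRs with ORFs free of internal stops. The latent (log-scale)
half-life is additive: 0.08 per ORF-internal junction per kb of ORF
(stabilizing), a fixed 61-codon weight vector (spread 3 per unit
frequency, drawn once from an internal constant seed — a study
constant, not per-run randomness), and two destabilizing 3'UTR motifs
— the AU-rich element core `UAUUUAU` (-0.4 per occurrence) and the
Pumilio element `UGUAAAUA` (-0.3) — with U-shaped positional weights
peaking at the 3'UTR termini, matching the positional behavior
established for these elements; plus Gaussian noise (sd 0.2). Every
contribution is recorded in a ledger that reconstructs each latent
exactly, so recovery tests have a ground truth. The component scales
were chosen once so that the three sequence-encoded terms contribute
comparably (~0.27 sd each) and dominate the noise.

The compendium generator observes each sample as
`distortion(latent + study effect + method-class bias + cell-type
effect + noise)` mapped onto a raw half-life scale
(hours = `10^(0.3 y + 0.8)`, median ~6 h), with a rank-preserving
monotone distortion `a x + b x^3` per sample, 30% missing cells (a
length-dependent option exists), gene-wise study and method-class
effects (the latter emulating genuine method bias such as
length-dependent labeling enrichment), units in hours or minutes, and
a couple of samples deposited as degradation rates so the
unit-handling path is exercised end to end.

What the generators deliberately do not emulate: realistic nucleotide
composition beyond a GC knob, isoform structure, expression-dependent
measurement error, or raw decay time courses. Passing recovery tests
therefore demonstrates the correctness of the pipeline's machinery on
data with the right effect structure — not performance on real
transcriptomes.

# Validation scales

The test suite runs everything at deliberately small problem sizes:
the consensus-recovery check uses the stated conditions (2000 genes x
20 samples, 30% missing, noise sd 0.5); the network's learning check
uses the scaled-down surrogate (3000 genes, 1024-nt encoder, 32
channels, at most 20 epochs on one CPU) with motif/codon interrogation
on a subset of valid mRNAs; unit tests use hand-built transcripts and
tiny seeded models. Full-scale training (12,288 nt, 64 channels,
fold x replicate ensembles) uses the identical code paths.

# Known limitations

* The compendium pipeline assumes a single dominant latent axis;
  PC2/PC3 are computed but deliberately not offered as phenotypes.
* EM-PCA imputation can converge slowly when the requested rank
  approaches the sample count on noisy data; the rank-selection CV
  therefore scores candidates with capped runs.
* The network trains on one CPU at useful speed only for scaled-down
  configurations; full-scale ensembles are compute-bound.
* Lasso interpretation under heavy collinearity identifies candidate
  sets, not individual causal features; the collinearity report is
  part of the output for exactly this reason.
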