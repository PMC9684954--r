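test_that("log transform applies unit-aware pseudocounts and fixes signs", {
  vals <- matrix(c(0.9, 2, 54, 6), 2, 2,
                 dimnames = list(c("g1", "g2"), c("hrs", "mins")))
  meta <- data.frame(sample_id = c("hrs", "mins"), study = "A",
                     species = "human", cell_type = "HeLa", method = "4sU",
                     unit = c("hours", "minutes"),
                     is_degradation_rate = FALSE)
  m <- preprocessHalflives(vals, meta)
  expect_s4_class(m, "HalfLifeMatrix")
  expect_equal(hlStage(m), "transformed")
  ## pseudocount 0.1 in hours forces log10(0.9 + 0.1) == 0 exactly
  expect_identical(hlValues(m)["g1", "hrs"], 0)
  ## pseudocount 1 in minutes
  expect_equal(hlValues(m)["g1", "mins"], log10(54 + 1))

  ## degradation rates: same transform then negation
  vals_r <- matrix(c(0.5, 2), 2, 1, dimnames = list(c("g1", "g2"), "r1"))
  meta_r <- data.frame(sample_id = "r1", study = "B", species = "human",
                       cell_type = "HeLa", method = "ActD",
                       unit = NA_character_, is_degradation_rate = TRUE)
  mr <- preprocessHalflives(vals_r, meta_r)
  expect_equal(hlValues(mr)[, 1],
               -log10(c(g1 = 0.5, g2 = 2) + 0.1))
})

test_that("duplicate gene IDs are averaged after transform", {
  vals <- matrix(c(10^1 - 0.1, 10^3 - 0.1), 2, 1,
                 dimnames = list(c("dup", "dup"), "s1"))
  meta <- data.frame(sample_id = "s1", study = "A", species = "human",
                     cell_type = "x", method = "4sU", unit = "hours",
                     is_degradation_rate = FALSE)
  m <- preprocessHalflives(vals, meta)
  expect_equal(nrow(hlValues(m)), 1L)
  expect_equal(unname(hlValues(m)["dup", "s1"]), 2)  # mean of log10 1 and 3
})

test_that("negative half-lives are rejected per record, unknown units error", {
  vals <- matrix(c(-1, 2), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  meta <- data.frame(sample_id = "s1", study = "A", species = "human",
                     cell_type = "x", method = "4sU", unit = "hours",
                     is_degradation_rate = FALSE)
  expect_warning(m <- preprocessHalflives(vals, meta), "negative")
  expect_true(is.na(hlValues(m)["g1", "s1"]))
  meta$unit <- "fortnights"
  expect_error(preprocessHalflives(vals, meta), "unit")
})

test_that("gene filter keeps exactly the sufficiently-measured genes", {
  counts <- c(3, 5, 10, 12, 54)
  n_s <- 60
  vals <- matrix(NA_real_, 5, n_s,
                 dimnames = list(sprintf("g%d", 1:5),
                                 sprintf("s%02d", 1:n_s)))
  for (i in 1:5) vals[i, seq_len(counts[i])] <- log10(1:counts[i] + 0.1)
  meta <- data.frame(sample_id = colnames(vals), study = "A",
                     species = "human", cell_type = "x", method = "4sU",
                     unit = "hours", is_degradation_rate = FALSE)
  m <- HalfLifeMatrix(vals, meta, stage = "transformed")
  expect_equal(rownames(hlValues(filterGenes(m, 10))),
               c("g3", "g4", "g5"))
  expect_equal(nrow(hlValues(filterGenes(m, 0))), 5L)   # identity
  expect_error(filterGenes(m, n_s + 1), "exceeds")
})

test_that("sample standardization gives mean 0, sd 1 on observed cells", {
  vals <- matrix(c(1, 2, 3, 5, NA, 9), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), study = "A",
                     species = "human", cell_type = "x", method = "4sU",
                     unit = "hours", is_degradation_rate = FALSE)
  m <- HalfLifeMatrix(vals, meta, stage = "filtered")
  z <- standardizeSamples(m)
  expect_equal(unname(hlValues(z)[, "s1"]), c(-1, 0, 1))
  expect_true(is.na(hlValues(z)["b", "s2"]))
  ## idempotence within tolerance
  z2 <- standardizeSamples(HalfLifeMatrix(hlValues(z), meta,
                                          stage = "filtered"))
  expect_equal(hlValues(z2), hlValues(z), tolerance = 1e-12)
  ## degenerate columns error, naming the sample
  bad <- vals; bad[, 2] <- 7
  mb <- HalfLifeMatrix(bad, meta, stage = "filtered")
  expect_error(standardizeSamples(mb), "s2")
})

test_that("z-scores are invariant to the log base of the transform", {
  x <- 10^rnorm(50)
  z10 <- scale(log10(x))[, 1]
  zln <- scale(log(x))[, 1]
  expect_lt(max(abs(z10 - zln)), 1e-10)
})

test_that("iterative PCA imputation recovers a masked rank-1 matrix", {
  set.seed(5)
  u <- rnorm(8); v <- rnorm(5)
  x <- tcrossprod(u, v)
  dimnames(x) <- list(sprintf("g%d", 1:8), sprintf("s%d", 1:5))
  mask <- withr::with_seed(7, matrix(runif(40) < 0.2, 8, 5))
  mask[1, ] <- FALSE; mask[, 1] <- FALSE  # keep rows/cols observed
  xm <- x; xm[mask] <- NA
  imp <- .pcaImputeFixed(xm, 1L, tol = 1e-9, max_iter = 2000L)
  ## oracle: rank-1 SVD of the unmasked matrix is the matrix itself
  expect_lt(max(abs(imp[mask] - x[mask])), 1e-6)
  ## observed cells bit-identical
  expect_identical(imp[!mask], x[!mask])
})

test_that("imputation wrapper enforces stage and degenerate inputs", {
  fx <- makeTinyCompendium()
  vals <- fx$values
  vals[sample(length(vals), 80)] <- NA
  m <- preprocessHalflives(vals, fx$meta)
  f <- filterGenes(m, 2)
  s <- standardizeSamples(f)
  out <- imputeIterativePCA(s, ncp_max = 3, seed = 1)
  expect_equal(hlStage(out$matrix), "imputed")
  expect_false(anyNA(hlValues(out$matrix)))
  expect_true(out$ncp %in% 0:3)
  obs <- !is.na(hlValues(s))
  expect_identical(hlValues(out$matrix)[obs], hlValues(s)[obs])
  ## a gene with no observations errors
  bad <- hlValues(s); bad[1, ] <- NA
  mb <- HalfLifeMatrix(bad, fx$meta, stage = "transformed")
  mb@stage <- "standardized"
  expect_error(imputeIterativePCA(mb, ncp_max = 2), "missing")
  ## matrix without missing values is returned unchanged
  full <- standardizeSamples(filterGenes(
    preprocessHalflives(fx$values, fx$meta), 2))
  out2 <- imputeIterativePCA(full, ncp_max = 2, ncp = 2)
  expect_identical(hlValues(out2$matrix), hlValues(full))
})

test_that("quantile normalization equalizes column distributions exactly", {
  vals <- cbind(s1 = c(1, 2, 3), s2 = c(6, 4, 5))
  rownames(vals) <- c("a", "b", "c")
  meta <- data.frame(sample_id = c("s1", "s2"), study = "A",
                     species = "human", cell_type = "x", method = "4sU",
                     unit = "hours", is_degradation_rate = FALSE)
  m <- HalfLifeMatrix(vals, meta, stage = "imputed")
  q <- quantileNormalize(m)
  expect_equal(hlStage(q), "normalized")
  expect_equal(unname(hlValues(q)[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(sort(unname(hlValues(q)[, "s2"])), c(2.5, 3.5, 4.5))
  ## identical columns are a fixed point
  same <- cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9))
  rownames(same) <- c("a", "b", "c")
  q2 <- quantileNormalize(HalfLifeMatrix(same, meta, stage = "imputed"))
  expect_equal(unname(hlValues(q2)), unname(same))
  ## exact column-identity postcondition on a random matrix
  set.seed(3)
  r <- matrix(rnorm(60), 12, 5,
              dimnames = list(sprintf("g%d", 1:12), sprintf("s%d", 1:5)))
  meta5 <- data.frame(sample_id = colnames(r), study = "A",
                      species = "human", cell_type = "x", method = "4sU",
                      unit = "hours", is_degradation_rate = FALSE)
  q3 <- hlValues(quantileNormalize(HalfLifeMatrix(r, meta5,
                                                  stage = "imputed")))
  ref <- unname(sort(q3[, 1]))
  for (j in 2:5) expect_identical(unname(sort(q3[, j])), ref)
  ## missing values refuse (constructed below stage to dodge validity)
  r[1, 1] <- NA
  mmiss <- HalfLifeMatrix(r, meta5, stage = "transformed")
  mmiss@stage <- "imputed"
  expect_error(quantileNormalize(mmiss), "missing")
})

test_that("consensus PC1 is sign-anchored and variance fractions are sane", {
  set.seed(11)
  u <- rnorm(30); v <- abs(rnorm(4)) + 0.5
  x <- tcrossprod(u, v)
  dimnames(x) <- list(sprintf("g%d", 1:30), sprintf("s%d", 1:4))
  meta <- data.frame(sample_id = colnames(x), study = "A",
                     species = "human", cell_type = "x", method = "4sU",
                     unit = "hours", is_degradation_rate = FALSE)
  m <- HalfLifeMatrix(x, meta, stage = "normalized")
  cons <- consensusPC1(m)
  ## exact rank-1: PC1 explains everything
  expect_equal(varianceExplained(cons)[1], 1, tolerance = 1e-10)
  expect_gt(cor(geneScores(cons), rowMeans(x)), 0)
  ## the anchor resolves the arbitrary PCA eigenvector sign: permuting
  ## sample columns (which can flip the raw eigenvector) cannot change
  ## the anchored scores
  mperm <- HalfLifeMatrix(x[, c(3, 1, 4, 2)], meta[c(3, 1, 4, 2), ],
                          stage = "normalized")
  expect_equal(geneScores(consensusPC1(mperm)), geneScores(cons),
               tolerance = 1e-10)
  ## and the anchor invariant always holds, whatever the input sign
  mneg <- HalfLifeMatrix(-x, meta, stage = "normalized")
  expect_gt(cor(geneScores(consensusPC1(mneg)), rowMeans(-x)), 0)
  ## fewer than 2 samples errors
  m1 <- HalfLifeMatrix(x[, 1, drop = FALSE], meta[1, ],
                       stage = "normalized")
  expect_error(consensusPC1(m1), "2 samples")
})

test_that("sample PCA gives duplicated samples identical coordinates", {
  fx <- makeTinyCompendium()
  vals <- fx$values
  vals[, 2] <- vals[, 1]
  m <- quantileNormalize(HalfLifeMatrix(
    scale(log10(vals + 0.1)), fx$meta, stage = "imputed"))
  sp <- samplePCA(m)
  expect_equal(sp$coords$PC1[1], sp$coords$PC1[2], tolerance = 1e-10)
  expect_equal(sp$coords$PC2[1], sp$coords$PC2[2], tolerance = 1e-10)
  expect_lte(sum(sp$variance_explained), 1 + 1e-8)
})

test_that("method-bias rank-sum test matches exact enumeration", {
  ## identical distributions: p = 1 under the exact method
  co <- data.frame(PC2 = c(1, 2, 3, 1, 2, 3),
                   study = sprintf("st%d", 1:6),
                   method_class = rep(c("pulse_labeling",
                                        "transcriptional_shutoff"),
                                      each = 3))
  r <- methodBiasTest(co)
  expect_equal(r$p.value, 1)
  ## complete separation of 3 vs 3: two-sided exact p = 2/20
  co$PC2 <- c(1, 2, 3, 4, 5, 6)
  r2 <- methodBiasTest(co)
  expect_equal(r2$p.value, 0.1)
  ## replicates of one study are averaged first
  co3 <- data.frame(PC2 = c(0.2, 0.4, 1, 2, 3, 4),
                    study = c("stA", "stA", "stB", "stC", "stD", "stE"),
                    method_class = c("pulse_labeling", "pulse_labeling",
                                     "pulse_labeling",
                                     rep("transcriptional_shutoff", 3)))
  r3 <- methodBiasTest(co3)
  expect_equal(sort(r3$groups$pulse_labeling), c(0.3, 1))
  ## fewer than 2 studies in a class errors
  expect_error(methodBiasTest(co3[c(1, 2, 4:6), ]), ">= 2")
})

test_that("cell-type specificity test partitions cross-study pairs", {
  ## 3 studies x 1 sample, two sharing a cell type ->
  ## 1 same-type and 2 different-type pairs
  vals <- matrix(rnorm(30), 10, 3,
                 dimnames = list(sprintf("g%d", 1:10),
                                 c("s1", "s2", "s3")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     study = c("A", "B", "C"), species = "human",
                     cell_type = c("HeLa", "HeLa", "K562"),
                     method = "4sU", unit = "hours",
                     is_degradation_rate = FALSE)
  m <- HalfLifeMatrix(vals, meta, stage = "normalized")
  r <- celltypeSpecificityTest(m)
  expect_equal(length(r$same), 1L)
  expect_equal(length(r$different), 2L)
  ## all samples from one study: no cross-study pairs
  meta1 <- meta; meta1$study <- "A"
  expect_error(celltypeSpecificityTest(
    HalfLifeMatrix(vals, meta1, stage = "normalized")), "cross-study")
})

test_that("the full pipeline is deterministic and recovers planted truth", {
  spec <- compendiumSpec(n_samples = 12L, n_studies = 6L,
                         missing_rate = 0.2)
  lat <- withr::with_seed(1, setNames(rnorm(300), sprintf("g%03d", 1:300)))
  cmp <- genCompendiumMatrix(lat, spec, seed = 8)
  run1 <- runConsensusPipeline(cmp$values, cmp$meta, min_samples = 4,
                               ncp_max = 4, seed = 2)
  run2 <- runConsensusPipeline(cmp$values, cmp$meta, min_samples = 4,
                               ncp_max = 4, seed = 2)
  expect_identical(geneScores(run1$consensus), geneScores(run2$consensus))
  common <- intersect(names(geneScores(run1$consensus)), names(lat))
  expect_gt(cor(geneScores(run1$consensus)[common], lat[common]), 0.8)
  ## planted method-class bias is detected on sample PC2
  spec_bias <- compendiumSpec(n_samples = 20L, n_studies = 10L,
                              method_class_sd = 1, missing_rate = 0.15)
  cmpb <- genCompendiumMatrix(lat, spec_bias, seed = 9)
  runb <- runConsensusPipeline(cmpb$values, cmpb$meta, min_samples = 4,
                               ncp_max = 4, seed = 2)
  ## gene centering removes the shared latent, and this synthetic has no
  ## dominant outlier study, so the planted class axis is the leading PC
  mb <- methodBiasTest(runb$sample_pca$coords, pc = "PC1")
  expect_lt(mb$p.value, 0.01)
  ## and the two classes are linearly separable on the (PC1, PC2) plane
  co <- runb$sample_pca$coords
  pulse <- co$method_class == "pulse_labeling"
  fit <- suppressWarnings(glm(pulse ~ PC1 + PC2, data = co,
                              family = binomial))
  expect_true(all((predict(fit) > 0) == pulse))
})
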