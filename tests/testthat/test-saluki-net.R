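test_that("the published configuration has exactly 155,521 parameters", {
  m <- buildSaluki(salukiHyperparams())
  expect_identical(salukiParamCount(m), 155521L)
  ## the count is a pure function of the hyperparameters
  m2 <- buildSaluki(salukiHyperparams(), seed = 99)
  expect_identical(salukiParamCount(m2), 155521L)
  ## halving the channels strictly decreases the count
  m32 <- buildSaluki(salukiHyperparams(channels = 32L))
  expect_lt(salukiParamCount(m32), salukiParamCount(m))
  ## both heads together carry one extra head block
  expect_gt(salukiParamCount(m, "all"), salukiParamCount(m))
  ## width constraint
  expect_error(salukiHyperparams(L_max = 1000L), "divisible")
})

test_that("compute kernels agree with the plain-R reference layers", {
  set.seed(51)
  B <- 4L; L <- 16L; k <- 5L
  for (Cin in c(3L, 12L)) {       # both the narrow and wide conv paths
    Cout <- 6L
    X <- matrix(rnorm(Cin * B * L), Cin, B * L)
    W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
    b <- rnorm(Cout)
    expect_equal(.cppConvForward(X, W, b, B, L, k),
                 .convForward(X, W, b, B, L, k), tolerance = 1e-12)
    dZ <- matrix(rnorm(Cout * B * L), Cout, B * L)
    got <- .cppConvBackward(dZ, X, W, B, L, k, TRUE)
    want <- .convBackward(dZ, X, W, B, L, k)
    expect_equal(got$dX, want$dX, tolerance = 1e-12)
    expect_equal(got$dW, want$dW, tolerance = 1e-12)
    expect_equal(as.numeric(got$db), want$db, tolerance = 1e-12)
  }
  ## fused layer-norm + ReLU against the composed reference
  C <- 8L; N <- 40L
  X <- matrix(rnorm(C * N), C, N)
  g <- runif(C, 0.5, 1.5); bt <- rnorm(C)
  fused <- .cppLnReluForward(X, g, bt, 1e-3)
  ref <- .lnForward(X, g, bt)
  expect_equal(fused$out, pmax(ref$out, 0), tolerance = 1e-12)
  expect_equal(fused$xhat, ref$xhat, tolerance = 1e-12)
  ## pooling kernel against the reference
  pf <- .cppPoolForward(X, 4L, 10L)
  pr <- .poolForward(X, 4L, 10L)
  expect_equal(pf$out, pr$out)
  dO <- matrix(rnorm(C * N / 2), C, N / 2)
  expect_equal(.cppPoolBackward(dO, pf$mask, 4L, 10L),
               .poolBackward(dO, pr$mask, 4L, 10L))
})

test_that("analytic gradients match finite differences end to end", {
  set.seed(7)
  h <- salukiHyperparams(L_max = 32L, channels = 4L, n_blocks = 3L,
                         dropout = 0, heads = c("human", "mouse"))
  m <- buildSaluki(h, seed = 3)
  B <- 3L
  tensors <- lapply(1:B, function(i) {
    t <- matrix(0, 32, 6)
    t[cbind(1:32, sample(1:4, 32, replace = TRUE))] <- 1
    t[sample(1:32, 2), 5] <- 1
    t[seq(4, 32, by = 3), 6] <- 1
    t
  })
  Xb <- .stackTensors(tensors, 1:B)
  y <- rnorm(B)
  loss_fn <- function(params) {
    fw <- .salukiForward(params, h, Xb, B, "mouse", TRUE, m@bnStats)
    mean((fw$pred - y)^2)
  }
  fw <- .salukiForward(m@params, h, Xb, B, "mouse", TRUE, m@bnStats)
  g <- .salukiBackward(m@params, h, fw$caches, 2 * (fw$pred - y) / B)
  for (nm in names(g)) {
    i <- which.max(abs(g[[nm]]))
    pp <- m@params; pp[[nm]][i] <- pp[[nm]][i] + 1e-6
    pm <- m@params; pm[[nm]][i] <- pm[[nm]][i] - 1e-6
    num <- (loss_fn(pp) - loss_fn(pm)) / 2e-6
    expect_lt(abs(num - g[[nm]][i]) /
                max(1e-6, abs(num) + abs(g[[nm]][i])), 1e-5)
  }
  ## the untouched head got no gradients
  expect_false(any(grepl("human", names(g))))
})

test_that("padding cannot influence predictions", {
  h <- salukiHyperparams(L_max = 64L, channels = 8L, n_blocks = 5L,
                         heads = "human")
  m <- buildSaluki(h, seed = 2)
  ## two fully-padded inputs give identical outputs
  z <- matrix(0, 64, 6)
  p <- .predictTensors(m, list(z, z), "human")
  expect_identical(p[1], p[2])
  ## broadcasting the same weights over a wider tensor leaves the
  ## prediction of an all-padding input unchanged (tower activations and
  ## the recurrent state stay exactly zero at initialization); for real
  ## content, same-padding convolutions bleed a few positions across the
  ## content/padding boundary, so exact width invariance is not a
  ## property of this architecture
  h128 <- salukiHyperparams(L_max = 128L, channels = 8L, n_blocks = 5L,
                            heads = "human")
  m128 <- new("SalukiModel", params = m@params, hyper = h128,
              bnStats = m@bnStats, log = list())
  p64 <- .predictTensors(m, list(matrix(0, 64, 6)), "human")
  p128 <- .predictTensors(m128, list(matrix(0, 128, 6)), "human")
  expect_equal(p64, p128, tolerance = 1e-10)
})

test_that("training is seeded-deterministic and improves on a tiny task", {
  set.seed(61)
  spec <- generativeSpec(n_genes = 150L, utr5_meanlog = log(30),
                         codons_meanlog = log(45),
                         utr3_meanlog = log(60), exon_lambda = 2)
  tx <- genTranscriptome(spec, seed = 3)
  lat <- genLatentHalflives(tx$ts, spec, seed = 4)
  enc <- encodeTranscripts(tx$ts, L_max = 256L, species = "human")
  folds <- assignHomologyFolds(geneIds(tx$ts), character(0),
                               n_folds = 5, seed = 2)$human
  h <- salukiHyperparams(L_max = 256L, channels = 8L, heads = "human",
                         batch = 32L)
  m1 <- trainSaluki(enc, lat$latent, list(human = folds), test_fold = 1,
                    hyper = h, seed = 11, max_epochs = 3)
  m2 <- trainSaluki(enc, lat$latent, list(human = folds), test_fold = 1,
                    hyper = h, seed = 11, max_epochs = 3)
  ## identical seeds give identical training trajectories and parameters
  expect_identical(m1@log$val_r, m2@log$val_r)
  expect_identical(m1@params, m2@params)
  expect_true(all(is.finite(m1@log$val_r)))
  ## zero-variance target refuses
  flat <- setNames(rep(1, length(lat$latent)), names(lat$latent))
  expect_error(trainSaluki(enc, flat, list(human = folds), test_fold = 1,
                           hyper = h, seed = 1, max_epochs = 1),
               "zero-variance")
})

test_that("two-species training updates a shared trunk with two heads", {
  set.seed(71)
  spec <- generativeSpec(n_genes = 80L, utr5_meanlog = log(25),
                         codons_meanlog = log(40),
                         utr3_meanlog = log(50), exon_lambda = 1)
  tx <- genTranscriptome(spec, seed = 5)
  lat <- genLatentHalflives(tx$ts, spec, seed = 6)
  sp <- rep(c("human", "mouse"), length.out = 80)
  enc <- encodeTranscripts(tx$ts, L_max = 256L, species = "human")
  enc@species <- sp
  folds <- setNames(rep_len(1:4, 80), geneIds(tx$ts))
  h <- salukiHyperparams(L_max = 256L, channels = 8L, batch = 16L)
  m <- trainSaluki(enc, lat$latent, folds, test_fold = 1, hyper = h,
                   seed = 9, max_epochs = 2)
  expect_s4_class(m, "SalukiModel")
  ## both heads produce (different) finite predictions
  ph <- predictSaluki(m, enc, species = "human")
  pm <- predictSaluki(m, enc, species = "mouse")
  expect_true(all(is.finite(ph)) && all(is.finite(pm)))
  expect_false(isTRUE(all.equal(unname(ph), unname(pm))))
})

test_that("ensembles average their members as documented", {
  set.seed(81)
  spec <- generativeSpec(n_genes = 60L, utr5_meanlog = log(25),
                         codons_meanlog = log(40),
                         utr3_meanlog = log(50), exon_lambda = 1)
  tx <- genTranscriptome(spec, seed = 7)
  lat <- genLatentHalflives(tx$ts, spec, seed = 8)
  enc <- encodeTranscripts(tx$ts, L_max = 256L, species = "human")
  folds <- setNames(rep_len(1:3, 60), geneIds(tx$ts))
  h <- salukiHyperparams(L_max = 256L, channels = 8L, batch = 16L,
                         heads = "human")
  ens <- trainSalukiEnsemble(enc, lat$latent, list(human = folds),
                             test_folds = 1:3, replicates = 1:2,
                             hyper = h, seed = 13, max_epochs = 1)
  expect_equal(length(ens@members), 6L)
  ## external mode equals the arithmetic mean over all members
  pext <- ensemblePredict(ens, enc, mode = "external", species = "human")
  indiv <- sapply(ens@members, function(m)
    predictSaluki(m, enc, species = "human"))
  expect_equal(unname(pext), unname(rowMeans(indiv)), tolerance = 1e-12)
  ## held-out mode averages exactly the replicates of the gene's fold
  phold <- ensemblePredict(ens, enc, mode = "heldout", species = "human")
  g1 <- which(folds[enc@geneId] == 1)
  mem1 <- which(ens@fold == 1)
  expect_equal(unname(phold[g1]),
               unname(rowMeans(indiv[g1, mem1, drop = FALSE])),
               tolerance = 1e-12)
  ## an ensemble missing a fold refuses external mode unless overridden
  part <- new("SalukiEnsemble", members = ens@members[1:2],
              fold = ens@fold[1:2], replicate = ens@replicate[1:2],
              folds = ens@folds, validationR = ens@validationR[1:2])
  expect_error(ensemblePredict(part, enc, mode = "external",
                               species = "human"), "incomplete")
  expect_silent(ensemblePredict(part, enc, mode = "external",
                                species = "human", allow_partial = TRUE))
})
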