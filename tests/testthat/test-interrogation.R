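## Mutational interrogation mechanics need no trained weights: deltas,
## coordinate bookkeeping and aggregation are tested on a seeded
## untrained model.

test_that("saturation mutagenesis produces coherent per-position deltas", {
  ts <- makeTinyTranscripts()
  m <- makeTinyModel(L_max = 64L)
  tr <- ism(m, ts, "t1", species = "human")
  L <- nchar(transcriptModel(ts, "t1")$seq)
  expect_equal(nrow(tr$delta), L)
  ## the reference base has no delta; the three alternatives do
  for (p in seq_len(L)) {
    expect_true(is.na(tr$delta[p, tr$ref[p]]))
    expect_equal(sum(!is.na(tr$delta[p, ])), 3L)
  }
  ## mean effect is the mean of the three alternatives
  expect_equal(tr$mean_effect, rowMeans(tr$delta, na.rm = TRUE))
  expect_equal(tr$abs_mean, abs(tr$mean_effect))
})

test_that("variant effects equal the matching mutagenesis entries", {
  ts <- makeTinyTranscripts()
  m <- makeTinyModel(L_max = 64L)
  tr <- ism(m, ts, "t1", species = "human")
  tm <- transcriptModel(ts, "t1")
  seqc <- strsplit(tm$seq, "")[[1]]
  vars <- data.frame(transcript_id = "t1", pos = c(0L, 5L, 17L),
                     ref = seqc[c(1, 6, 18)], alt = c("G", "U", "C"))
  ve <- variantEffect(m, ts, vars, species = "human")
  for (i in 1:3)
    expect_equal(ve$delta[i],
                 unname(tr$delta[vars$pos[i] + 1L, vars$alt[i]]),
                 tolerance = 1e-9)
  ## a wrong reference allele is refused with the observed base named
  bad <- data.frame(transcript_id = "t1", pos = 0L, ref = "G", alt = "A")
  expect_error(variantEffect(m, ts, bad), "mismatch")
})

test_that("track smoothing is a shrinking centered moving average", {
  expect_equal(smoothTrack(rep(2, 10), 8), rep(2, 10))
  x <- c(1, 2, 3, 4)
  expect_equal(smoothTrack(x, 3)[2], mean(x[1:3]))
  expect_equal(smoothTrack(x, 3)[1], mean(x[1:2]))   # shrunk edge
})

test_that("metagene aggregation bins positions and quartiles correctly", {
  ts <- makeTinyTranscripts()
  ## synthetic tracks: all-zero effects give an all-zero metagene
  mk_track <- function(id, val) {
    L <- nchar(transcriptModel(ts, id)$seq)
    list(delta = matrix(val, L, 4), mean_effect = rep(val, L),
         abs_mean = rep(abs(val), L),
         ref = rep("A", L), offset = 0L, prediction = val,
         transcript_id = id)
  }
  tracks <- list(t1 = mk_track("t1", 0), t2 = mk_track("t2", 0))
  preds <- c(t1 = 0.1, t2 = 0.9)
  mg <- ismMetagene(tracks, ts, preds, n_quartiles = 2, n_pct_bins = 4)
  expect_true(all(mg[!is.na(mg)] == 0))
  ## each transcript contributes to exactly one quartile row
  tracks2 <- list(t1 = mk_track("t1", 1), t2 = mk_track("t2", 2))
  mg2 <- ismMetagene(tracks2, ts, preds, n_quartiles = 2, n_pct_bins = 4)
  expect_true(all(mg2[1, , ][!is.na(mg2[1, , ])] == 1))
  expect_true(all(mg2[2, , ][!is.na(mg2[2, , ])] == 2))
  ## permutation invariance in the transcript input order
  mg3 <- ismMetagene(rev(tracks2), ts, preds, n_quartiles = 2,
                     n_pct_bins = 4)
  expect_equal(mg2, mg3)
})

test_that("insertional scans preserve length and skip identical inserts", {
  ts <- makePolyATranscript()
  m <- makeTinyModel(L_max = 2048L)
  ## inserting a k-mer identical to the reference changes nothing:
  ## deltas are exactly zero in the all-A regions
  sc <- insertMotifScan(m, ts, "AAAAAAA", bins = 10L, species = "human")
  expect_true(all(abs(sc$mean_delta["utr3", ]) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(sc$mean_delta["utr5", ]) < 1e-12, na.rm = TRUE))
  expect_equal(sc$n_mrna, 1L)
  ## the validity filter rejects short regions
  short <- makeTinyTranscripts()
  expect_error(insertMotifScan(m, short, "UAUUUAU"), "no valid mRNAs")
  ## codon scan: inserting the codon already present gives zero deltas
  ## (except the first bin, whose in-frame anchor is the AUG itself)
  cs <- insertCodonScan(m, ts, codons = "AAA", bins = 5L,
                        species = "human")
  expect_true(all(abs(cs$profile[, -1]) < 1e-12, na.rm = TRUE))
  ## splice-site scan returns one delta row per region
  ss <- insertSpliceSiteScan(m, ts, bins = 5L, species = "human")
  expect_equal(rownames(ss$mean_delta), c("utr5", "orf", "utr3"))
  expect_true(any(is.finite(ss$mean_delta)))
})

test_that("reporter scoring integrates fragments into the scaffold", {
  sc <- syntheticReporterScaffold(seed = 4)
  m <- makeTinyModel(L_max = 2048L)
  base <- reporterEffect(m, sc, "", species = "human")
  ## empty fragment: the scaffold baseline
  enc <- encodeMrna(sc$seq, sc$utr5_len, sc$orf_len, sc$junctions,
                    2048L)
  expect_equal(base, .predictTensors(m, list(enc$tensor), "human"))
  ## two fragments differing at one base reproduce the variant effect
  ## computed on the chimeric transcript
  f1 <- "ACGUACGUAC"; f2 <- "ACGAACGUAC"
  d_rep <- reporterEffect(m, sc, f2) - reporterEffect(m, sc, f1)
  chim_seq <- paste0(substr(sc$seq, 1, sc$insertion_site), f1,
                     substr(sc$seq, sc$insertion_site + 1,
                            nchar(sc$seq)))
  chim <- TranscriptSet(seq = c(ch = chim_seq), geneId = "ch",
                        utr5Len = sc$utr5_len, orfLen = sc$orf_len,
                        utr3Len = nchar(chim_seq) - sc$utr5_len -
                          sc$orf_len)
  v <- data.frame(transcript_id = "ch", pos = sc$insertion_site + 3L,
                  ref = "U", alt = "A")
  d_var <- variantEffect(m, chim, v, species = "human")$delta
  expect_equal(d_rep, d_var, tolerance = 1e-12)
  ## a scaffold without an insertion site refuses
  expect_error(reporterScaffold("AUGAAAUAAGGG", 0, 9, NA), "insertion")
})

test_that("the matched variant benchmark pairs and ranks correctly", {
  ## perfect separation gives AUROC 1, total ties give 0.5
  v <- data.frame(gene = sprintf("g%d", 1:8),
                  region = "utr3",
                  pip = c(0.95, 0.99, 0.92, rep(0.001, 5)),
                  expression = c(5, 6, 7, 5.1, 6.1, 7.1, 20, 30),
                  score = c(0.9, 0.8, 0.7, 0.1, 0.2, 0.05, 0.0, 0.0))
  r <- matchedVariantBenchmark(v)
  expect_equal(r$auroc, 1)
  ## expression matching picks the closest unused negative
  expect_equal(r$pairs$negative[1], 4L)
  v2 <- v; v2$score <- 1
  expect_equal(matchedVariantBenchmark(v2)$auroc, 0.5)
  ## a fully separated 3-vs-3 instance enumerates to 9/9
  vsep <- data.frame(gene = sprintf("g%d", 1:6), region = "orf",
                     pip = c(0.95, 0.95, 0.95, 0.001, 0.001, 0.001),
                     expression = 1:6,
                     score = c(0.9, 0.8, 0.7, 0.6, 0.65, 0.1))
  expect_equal(matchedVariantBenchmark(vsep)$auroc, 1)
  ## the 3-vs-3 instance with one inversion: the oracle is exhaustive
  ## pair enumeration, which gives 7/9 for these scores
  v3 <- data.frame(gene = sprintf("g%d", 1:6), region = "orf",
                   pip = c(0.95, 0.95, 0.95, 0.001, 0.001, 0.001),
                   expression = 1:6,
                   score = c(0.9, 0.8, 0.7, 0.6, 0.85, 0.1))
  r3 <- matchedVariantBenchmark(v3)
  enum <- mean(outer(r3$positive_scores, r3$negative_scores,
                     function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(r3$auroc, enum)
  expect_equal(r3$auroc, 7 / 9)
  ## unmatched positives are an error
  v4 <- v3; v4$region[4:6] <- "utr3"
  expect_error(matchedVariantBenchmark(v4), "insufficient")
})

test_that("midrank AUROC equals pair enumeration on random instances", {
  set.seed(91)
  for (i in 1:20) {
    pos <- sample(0:5, sample(2:6, 1), replace = TRUE)
    neg <- sample(0:5, sample(2:6, 1), replace = TRUE)
    enum <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(saluki:::.aucMidrank(pos, neg), enum)
  }
})
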