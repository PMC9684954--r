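test_that("basic features match hand computations", {
  ts <- makeTinyTranscripts()
  b <- basicFeatures(ts)
  expect_equal(dim(b), c(2L, 8L))
  ## t1: junctions at 7 (inside ORF (6, 18)) and 16 (inside) -> 2 junctions
  ## over 12 nt of ORF = 2 / 0.012 kb
  expect_equal(unname(b["gA", "orf_junction_density"]), 2 / 0.012)
  expect_equal(unname(b["gB", "orf_junction_density"]), 0)
  ## length transforms: log10(x + 0.1)
  expect_equal(unname(b["gA", "utr3_len"]), log10(10.1))
  expect_equal(unname(b["gB", "intron_len"]), log10(0.1))
  ## GC content of t1 utr5 ACGUAC: 3/6
  expect_equal(unname(b["gA", "utr5_gc"]), 0.5)
  ## an empty region yields missing GC and length log10(0.1)
  ts0 <- TranscriptSet(seq = c(t = "AUGAAAUAA"), geneId = "g",
                       utr5Len = 0L, orfLen = 9L, utr3Len = 0L)
  b0 <- basicFeatures(ts0)
  expect_true(is.na(b0[1, "utr5_gc"]))
  expect_equal(unname(b0[1, "utr5_len"]), -1)   # log10(0 + 0.1)
})

test_that("codon frequencies are normalized over all codons, stops dropped", {
  ts <- TranscriptSet(seq = c(t = "AUGAAAAAAUAG"), geneId = "g",
                      utr5Len = 0L, orfLen = 12L, utr3Len = 0L)
  f <- codonFrequencies(ts)
  expect_equal(ncol(f), 61L)
  expect_equal(unname(f[1, "codon_AAA"]), 0.5)   # 2 of 4 codons
  expect_equal(unname(f[1, "codon_AUG"]), 0.25)
  expect_false("codon_UAG" %in% colnames(f))
  expect_equal(unname(rowSums(f)), 0.75)         # 1 - stop fraction
  ## codons containing N drop out of numerator and denominator
  tsn <- TranscriptSet(seq = c(t = "AUGANAAAAUAG"), geneId = "g",
                       utr5Len = 0L, orfLen = 12L, utr3Len = 0L)
  fn <- codonFrequencies(tsn)
  expect_equal(unname(fn[1, "codon_AUG"]), 1 / 3)
})

test_that("k-mer frequencies have the documented dimension and sums", {
  ts <- makeTinyTranscripts()
  f <- kmerFrequencies(ts, "utr3")
  expect_equal(ncol(f), 21844L)
  ## frequencies within each k sum to 1 when the region is long enough
  for (k in 1:3) {
    sel <- nchar(sub("^utr3_", "", colnames(f))) == k
    expect_equal(unname(rowSums(f[, sel])), c(1, 1), tolerance = 1e-12)
  }
  ## region "AAAA": the only 2-mer is AA
  ts2 <- TranscriptSet(seq = c(t = paste0("AUGUUUUAA", "AAAA")),
                       geneId = "g", utr5Len = 0L, orfLen = 9L,
                       utr3Len = 4L)
  f2 <- kmerFrequencies(ts2, "utr3", k_range = 2)
  expect_equal(unname(f2[1, "utr3_AA"]), 1)
  expect_equal(sum(f2), 1)
  ## k-mers longer than the region count 0
  f7 <- kmerFrequencies(ts2, "utr3", k_range = 7)
  expect_true(all(f7 == 0))
})

test_that("windowed score averaging tiles, pads and normalizes", {
  ## region of 100 nt with a constant predictor returning 1 per window:
  ## two windows, sum 2, divided by the region length
  ts <- TranscriptSet(
    seq = c(t = paste0(strrep("A", 100), "AUGUUUUAA", strrep("C", 20))),
    geneId = "g", utr5Len = 100L, orfLen = 9L, utr3Len = 20L)
  widths <- integer()
  pred <- function(wins) {
    widths <<- c(widths, nchar(wins))
    matrix(1, length(wins), 1, dimnames = list(NULL, "f1"))
  }
  out <- windowAverageScores(ts, "utr5", pred, window = 50L, flank = 475L)
  expect_equal(unname(out[1, "f1"]), 2 / 100)
  ## every padded window is 1000 nt in the 475-flank mode
  expect_true(all(widths == 1000L))
  ## the first window starts at the transcript boundary: N-padded 5' side
  first_win <- NULL
  pred2 <- function(wins) {
    if (is.null(first_win)) first_win <<- wins[1]
    matrix(0, length(wins), 1, dimnames = list(NULL, "f1"))
  }
  windowAverageScores(ts, "utr5", pred2, window = 50L, flank = 50L)
  expect_equal(substr(first_win, 1, 50), strrep("N", 50))
  expect_equal(nchar(first_win), 150L)
})

test_that("peak counting is strand-aware and log-transformed", {
  genes <- GenomicRanges::GRanges(c("chr1", "chr1"),
                                  IRanges::IRanges(c(1, 2001),
                                                   c(1000, 3000)),
                                  strand = c("+", "-"))
  names(genes) <- c("g1", "g2")
  mk <- function(starts, strand)
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(starts, starts + 10),
                           strand = strand)
  peaks <- list(f99 = mk(seq(1, 990, by = 10), "+"),     # 99 peaks on g1+
                fopp = mk(c(10, 500), "-"))              # wrong strand
  pc <- peakCountFeatures(genes, peaks)
  expect_equal(unname(pc$values["g1", "f99"]), 2)        # log10(100)
  expect_equal(unname(pc$values["g1", "fopp"]), 0)       # log10(0 + 1)
  expect_equal(unname(pc$values["g2", "f99"]), 0)
})

test_that("overlap counting agrees with a brute-force checker", {
  set.seed(31)
  for (rep in 1:5) {
    ng <- sample(5:20, 1); np <- sample(20:200, 1)
    gs <- sort(sample(1:5000, ng))
    genes <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(gs, gs + sample(50:400, ng, TRUE)),
                                    strand = sample(c("+", "-"), ng, TRUE))
    names(genes) <- sprintf("g%d", seq_len(ng))
    ps <- sample(1:5500, np)
    peaks <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(ps, ps + sample(5:100, np, TRUE)),
                                    strand = sample(c("+", "-"), np, TRUE))
    got <- peakCountFeatures(genes, list(f = peaks))$values[, "f"]
    ## brute force O(n*m) interval check
    want <- vapply(seq_len(ng), function(i) {
      s1 <- GenomicRanges::start(genes)[i]; e1 <- GenomicRanges::end(genes)[i]
      st1 <- as.character(GenomicRanges::strand(genes))[i]
      hits <- sum(GenomicRanges::start(peaks) <= e1 &
                    GenomicRanges::end(peaks) >= s1 &
                    as.character(GenomicRanges::strand(peaks)) == st1)
      log10(hits + 1)
    }, numeric(1))
    expect_equal(unname(got), want)
  }
})

test_that("score-table ingestion transforms and maps to the universe", {
  tab <- data.frame(gene_id = c("g1", "g2", "g2"),
                    miR1 = c(-0.3, -0.5, -0.7))
  expect_warning(
    out <- ingestScoreTable(tab, c("g1", "g2", "g3"), group = "M",
                            transform = "negate"),
    "duplicate")
  expect_equal(unname(out$values["g1", "miR1"]), 0.3)
  expect_equal(unname(out$values["g2", "miR1"]), 0.6)  # mean then negate
  expect_true(is.na(out$values["g3", "miR1"]))
  ## identity passes through bit-exactly
  tab2 <- data.frame(gene_id = "g1", sc = pi)
  out2 <- ingestScoreTable(tab2, "g1", group = "R")
  expect_identical(unname(out2$values["g1", "sc"]), pi)
})

test_that("feature imputation recovers exact linear structure", {
  set.seed(13)
  n <- 80
  anchors <- matrix(rnorm(n * 3), n, 3,
                    dimnames = list(sprintf("g%d", 1:n),
                                    c("a1", "a2", "a3")))
  y <- drop(anchors %*% c(2, -1, 0.5)) + 3
  mask <- sample(n, 16)
  ycol <- y; ycol[mask] <- NA
  vals <- cbind(anchors, lin = ycol,
                dead = rep(NA_real_, n))
  f <- FeatureTable(vals, c("B", "B", "B", "R", "R"))
  expect_warning(out <- imputeFeatureMissing(f, c("a1", "a2", "a3")),
                 "all-missing")
  got <- featureValues(out)
  expect_false("dead" %in% colnames(got))
  expect_lt(max(abs(got[mask, "lin"] - y[mask])), 1e-6)
  ## observed cells untouched
  expect_identical(got[-mask, "lin"], y[-mask])
  ## no missing values: identity
  f2 <- FeatureTable(vals[, 1:3], c("B", "B", "B"))
  expect_identical(featureValues(imputeFeatureMissing(f2, "a1")),
                   vals[, 1:3])
})

test_that("feature assembly matches the published group cardinalities", {
  ts <- makeTinyTranscripts()
  f <- buildFeatureTable(ts, c("B", "C", "3"))
  tab <- table(featureGroups(f))
  expect_equal(unname(tab[["B"]]), 8L)
  expect_equal(unname(tab[["C"]]), 61L)
  expect_equal(unname(tab[["3"]]), 21844L)
  ## frequency features live in [0, 1]
  kv <- featureValues(f)[, featureGroups(f) %in% c("C", "3")]
  expect_true(all(kv >= 0 & kv <= 1, na.rm = TRUE))
})
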