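## Shared fixture builders. Everything is generated in code, seeded.

## A small complete half-life matrix with balanced study/method structure.
makeTinyCompendium <- function(n_genes = 60, n_samples = 8, seed = 42) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    samples <- sprintf("s%02d", seq_len(n_samples))
    latent <- rnorm(n_genes)
    vals <- sapply(seq_len(n_samples), function(j)
      10^(0.3 * (latent + rnorm(n_genes, sd = 0.3)) + 0.8))
    dimnames(vals) <- list(genes, samples)
    meta <- data.frame(
      sample_id = samples,
      study = rep(sprintf("st%d", 1:(n_samples / 2)), each = 2),
      species = "human",
      cell_type = rep(c("HeLa", "K562"), length.out = n_samples),
      method = rep(c("4sU", "ActD"), length.out = n_samples),
      unit = "hours", is_degradation_rate = FALSE,
      stringsAsFactors = FALSE)
    list(values = vals, meta = meta, latent = latent)
  })
}

## A hand-built TranscriptSet with known structure.
## t1: utr5 = 6 nt, orf = 12 nt (AUG GCC AAA UAA), utr3 = 10 nt,
##     junctions at 6 and 12 (both inside/boundary cases), intron 100.
## t2: single exon, utr5 empty-ish minimal.
makeTinyTranscripts <- function() {
  s1 <- paste0("ACGUAC", "AUGGCCAAAUAA", "GCGCAUAUAU")
  s2 <- paste0("GG", "AUGAAAAAAUAG", "CCCC")
  TranscriptSet(seq = c(t1 = s1, t2 = s2),
                geneId = c("gA", "gB"),
                utr5Len = c(6L, 2L), orfLen = c(12L, 12L),
                utr3Len = c(10L, 4L),
                junctions = list(c(7L, 16L), integer()),
                intronLenTotal = c(100L, 0L))
}

## A poly-A-rich transcript set passing the insertional-scan validity
## filter (5'UTR >= 100, ORF >= 500, 3'UTR >= 500 nt).
makePolyATranscript <- function() {
  utr5 <- strrep("A", 120)
  orf <- paste0("AUG", strrep("A", 498), "UAA")   # 504 nt, AAA codons
  utr3 <- strrep("A", 520)
  TranscriptSet(seq = c(tp = paste0(utr5, orf, utr3)),
                geneId = "gP", utr5Len = 120L, orfLen = 504L,
                utr3Len = 520L, junctions = list(integer()),
                intronLenTotal = 0L)
}

## A small untrained model for interrogation mechanics (deltas need no
## learned weights).
makeTinyModel <- function(L_max = 2048L, channels = 8L, seed = 9) {
  buildSaluki(salukiHyperparams(L_max = L_max, channels = channels,
                                heads = "human", dropout = 0.3,
                                n_blocks = min(7L, round(log2(L_max)) - 3L)),
              seed = seed)
}
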