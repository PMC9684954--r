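## Probing a trained model: in-silico saturation mutagenesis, metagene
## aggregation, insertional scans, variant / reporter scoring, and the
## matched variant-set benchmark. Effect sign is Delta = alt - ref
## everywhere: negative means destabilizing.

.BASES <- c("A", "C", "G", "U")

## A closure predicting a list of tensors with either a single model or an
## ensemble (external mode: mean over all members).
.tensorPredictor <- function(model, species) {
  if (is(model, "SalukiEnsemble")) {
    members <- model@members
    function(tensors) {
      ps <- vapply(members, function(m)
        .predictTensors(m, tensors, species), numeric(length(tensors)))
      rowMeans(matrix(ps, ncol = length(members)))
    }
  } else {
    function(tensors) .predictTensors(model, tensors, species)
  }
}

## Substitute the nucleotide channels at encoded positions `pos` (rows)
## with one-hot `bases`; auxiliary tracks are left untouched.
.mutateTensor <- function(tensor, pos, bases) {
  tensor[pos, 1:4] <- 0
  ch <- .NT_CHANNELS[bases]
  ok <- !is.na(ch)
  tensor[cbind(pos[ok], ch[ok])] <- 1
  tensor
}

#' In-silico saturation mutagenesis of one transcript
#'
#' For every encoded position, the reference base is mutated to each of
#' the three alternatives and the change in predicted half-life is
#' recorded. Auxiliary tracks (codon frame, splice) are held fixed even
#' for stop-gain mutations, so effects reflect the nucleotide change
#' alone.
#'
#' @param model A \linkS4class{SalukiModel} or \linkS4class{SalukiEnsemble}.
#' @param ts A \linkS4class{TranscriptSet}.
#' @param i Transcript index or ID.
#' @param species Head to use.
#' @param batch Mutant batch size for inference (512).
#' @return List of class contents: \code{delta} (L x 4 matrix over
#'   A/C/G/U, \code{NA} at the reference base), \code{mean_effect}
#'   (per-position mean of the three alternatives), \code{abs_mean},
#'   \code{ref} (reference base per position), \code{offset} (5'
#'   truncation offset in transcript coordinates), and \code{prediction}
#'   (the reference prediction).
#' @export
ism <- function(model, ts, i, species = "human", batch = 512L) {
  hyper <- if (is(model, "SalukiEnsemble")) model@members[[1]]@hyper
           else model@hyper
  tm <- transcriptModel(ts, i)
  enc <- encodeMrna(tm$seq, tm$utr5_len, tm$orf_len, tm$junctions,
                    hyper$L_max)
  predict_ <- .tensorPredictor(model, species)
  ref_pred <- predict_(list(enc$tensor))
  L <- enc$true_length
  offset <- max(0L, nchar(tm$seq) - hyper$L_max)
  ref_chars <- strsplit(substr(chartr("T", "U", toupper(tm$seq)),
                               offset + 1L, nchar(tm$seq)), "")[[1]]
  delta <- matrix(NA_real_, L, 4L, dimnames = list(NULL, .BASES))
  jobs <- do.call(rbind, lapply(seq_len(L), function(p) {
    alts <- setdiff(.BASES, ref_chars[p])
    cbind(pos = rep(p, length(alts)), alt = match(alts, .BASES))
  }))
  k <- 1L
  while (k <= nrow(jobs)) {
    j2 <- min(k + batch - 1L, nrow(jobs))
    tensors <- lapply(k:j2, function(r)
      .mutateTensor(enc$tensor, jobs[r, "pos"], .BASES[jobs[r, "alt"]]))
    preds <- predict_(tensors)
    delta[jobs[k:j2, , drop = FALSE]] <- preds - ref_pred
    k <- j2 + 1L
  }
  mean_effect <- rowMeans(delta, na.rm = TRUE)
  list(delta = delta, mean_effect = mean_effect,
       abs_mean = abs(mean_effect), ref = ref_chars, offset = offset,
       prediction = ref_pred, transcript_id = tm$transcript_id)
}

#' Smooth a per-position track
#'
#' Centered moving average with a window shrinking at the edges.
#'
#' @param x Numeric vector.
#' @param window Window width (8 in the variant-track convention).
#' @return Numeric vector of the same length.
#' @export
smoothTrack <- function(x, window = 8L) {
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half_lo):min(n, i + half_hi)]), numeric(1))
}

#' Metagene aggregation of mutagenesis tracks
#'
#' Transcripts are grouped into quartile bins of their predicted
#' half-life; per position the absolute mean effect is mapped to a
#' percentile bin within its functional region; values are averaged
#' within (quartile, region, bin).
#'
#' @param tracks Named list of \code{\link{ism}} results (names are
#'   transcript IDs).
#' @param ts The \linkS4class{TranscriptSet} the tracks came from.
#' @param predictions Named numeric predicted half-lives (one per track).
#' @param n_quartiles Number of half-life bins (4).
#' @param n_pct_bins Number of percentile bins per region (20).
#' @return A \code{quartile x region x bin} array of mean absolute
#'   effects (NA where no positions fell).
#' @export
ismMetagene <- function(tracks, ts, predictions, n_quartiles = 4L,
                        n_pct_bins = 20L) {
  ids <- names(tracks)
  stopifnot(!is.null(ids), all(ids %in% names(predictions)))
  qs <- stats::quantile(predictions[ids],
                        probs = seq(0, 1, length.out = n_quartiles + 1L))
  quart <- pmin(pmax(findInterval(predictions[ids], qs,
                                  rightmost.closed = TRUE), 1L),
                n_quartiles)
  regions <- c("utr5", "orf", "utr3")
  sums <- counts <- array(0, dim = c(n_quartiles, 3L, n_pct_bins),
                          dimnames = list(NULL, regions, NULL))
  lens <- regionLengths(ts)
  rownames(lens) <- transcriptIds(ts)
  for (w in seq_along(ids)) {
    tr <- tracks[[w]]
    tl <- lens[tr$transcript_id, ]
    bounds <- cumsum(c(0, tl))            # transcript coords, 0-based
    pos_tx <- seq_along(tr$abs_mean) + tr$offset  # 1-based transcript pos
    for (r in 1:3) {
      sel <- pos_tx > bounds[r] & pos_tx <= bounds[r + 1]
      if (!any(sel)) next
      rel <- (pos_tx[sel] - bounds[r] - 1) / tl[r]
      bin <- pmin(floor(rel * n_pct_bins) + 1L, n_pct_bins)
      v <- tr$abs_mean[sel]
      for (bb in unique(bin)) {
        sums[quart[w], r, bb] <- sums[quart[w], r, bb] + sum(v[bin == bb])
        counts[quart[w], r, bb] <- counts[quart[w], r, bb] +
          sum(bin == bb)
      }
    }
  }
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out
}

## Shared machinery of the insertional scans. For each valid transcript
## and each positional bin, `mutate(tensor, anchor_encoded)` produces the
## perturbed tensor (or NULL to skip a partial fit at the region end).
.insertionScan <- function(model, ts, species, regions, bins, span,
                           mutate, min_utr5 = 100L, min_orf = 500L,
                           min_utr3 = 500L, batch = 512L) {
  hyper <- if (is(model, "SalukiEnsemble")) model@members[[1]]@hyper
           else model@hyper
  lens <- regionLengths(ts)
  valid <- lens[, "utr5"] >= min_utr5 & lens[, "orf"] >= min_orf &
    lens[, "utr3"] >= min_utr3
  if (!any(valid)) stop("no valid mRNAs pass the length filter")
  idx <- which(valid)
  sums <- counts <- matrix(0, length(regions), bins,
                           dimnames = list(regions, NULL))
  for (i in idx) {
    tm <- transcriptModel(ts, i)
    enc <- encodeMrna(tm$seq, tm$utr5_len, tm$orf_len, tm$junctions,
                      hyper$L_max)
    offset <- max(0L, nchar(tm$seq) - hyper$L_max)
    predict_ <- .tensorPredictor(model, species)
    wt <- predict_(list(enc$tensor))
    bounds <- cumsum(c(0, tm$utr5_len, tm$orf_len, tm$utr3_len))
    names(bounds) <- c("utr5", "orf", "utr3", "end")
    jobs <- list(); where <- list()
    for (r in regions) {
      ri <- match(r, c("utr5", "orf", "utr3"))
      rlen <- c(tm$utr5_len, tm$orf_len, tm$utr3_len)[ri]
      for (b in seq_len(bins)) {
        anchor_tx <- bounds[ri] + floor((b - 1L) * rlen / bins) + 1L
        anchor_enc <- anchor_tx - offset
        if (anchor_enc < 1L) next
        if (anchor_tx + span - 1L > bounds[ri + 1L]) next  # partial fit
        mt <- mutate(enc$tensor, anchor_enc, tm, anchor_tx)
        if (is.null(mt)) next
        jobs[[length(jobs) + 1L]] <- mt
        where[[length(where) + 1L]] <- c(match(r, regions), b)
      }
    }
    if (!length(jobs)) next
    preds <- numeric(length(jobs))
    k <- 1L
    while (k <= length(jobs)) {
      j2 <- min(k + batch - 1L, length(jobs))
      preds[k:j2] <- predict_(jobs[k:j2])
      k <- j2 + 1L
    }
    for (q in seq_along(jobs)) {
      wz <- where[[q]]
      sums[wz[1], wz[2]] <- sums[wz[1], wz[2]] + (preds[q] - wt)
      counts[wz[1], wz[2]] <- counts[wz[1], wz[2]] + 1
    }
  }
  mean_delta <- sums / counts
  mean_delta[counts == 0] <- NA_real_
  list(mean_delta = mean_delta, n = counts, n_mrna = length(idx))
}

#' Insertional scan of a k-mer across positional bins
#'
#' For every valid mRNA (5'UTR >= 100 nt, ORF >= 500 nt, 3'UTR >= 500 nt),
#' each of 50 evenly divided positional bins per functional region, the
#' reference sequence at the bin's anchor is replaced by the k-mer (length
#' preserved) and the change in predicted half-life relative to wild type
#' is recorded, then averaged per bin across mRNAs.
#'
#' @param model Model or ensemble.
#' @param ts A \linkS4class{TranscriptSet}.
#' @param kmer Element to insert (A/C/G/U string).
#' @param bins Bins per region (50).
#' @param species Head to use.
#' @param regions Regions to scan (default all three).
#' @param ... Validity-filter and batching overrides passed to the scan
#'   engine.
#' @return List with \code{mean_delta} (region x bin), \code{n}
#'   (contributions per bin) and \code{n_mrna}.
#' @export
insertMotifScan <- function(model, ts, kmer, bins = 50L,
                            species = "human",
                            regions = c("utr5", "orf", "utr3"), ...) {
  kmer <- chartr("T", "U", toupper(kmer))
  if (grepl("[^ACGU]", kmer)) stop("kmer must be over A/C/G/U")
  kl <- nchar(kmer)
  kb <- strsplit(kmer, "")[[1]]
  mutate <- function(tensor, anchor_enc, tm, anchor_tx)
    .mutateTensor(tensor, anchor_enc:(anchor_enc + kl - 1L), kb)
  .insertionScan(model, ts, species, regions, bins, span = kl,
                 mutate = mutate, ...)
}

#' Insertional scan of a splice site
#'
#' Marks a single position of the splice track (an exon junction) at each
#' bin anchor instead of editing the sequence; the established behavior of
#' splice sites is stabilizing, so positive deltas recover the planted
#' sign.
#'
#' @inheritParams insertMotifScan
#' @return As \code{\link{insertMotifScan}}.
#' @export
insertSpliceSiteScan <- function(model, ts, bins = 50L, species = "human",
                                 regions = c("utr5", "orf", "utr3"), ...) {
  mutate <- function(tensor, anchor_enc, tm, anchor_tx) {
    if (tensor[anchor_enc, 5L] == 1) return(NULL)  # existing junction
    tensor[anchor_enc, 5L] <- 1
    tensor
  }
  .insertionScan(model, ts, species, regions, bins, span = 1L,
                 mutate = mutate, ...)
}

#' Insertional scan of the 61 non-stop codons
#'
#' Identical to the k-mer scan but restricted to the ORF, with each codon
#' inserted at the first in-frame codon start within each of 50 ORF bins.
#' Also returns the per-codon mean over all ORF bins (the quantity
#' comparable to codon stability coefficients).
#'
#' @param model Model or ensemble.
#' @param ts A \linkS4class{TranscriptSet}.
#' @param codons Codons to insert (default: all 61 non-stop codons).
#' @param bins ORF bins (50).
#' @param species Head to use.
#' @param ... Overrides for the scan engine.
#' @return List with \code{profile} (codon x bin matrix of mean deltas)
#'   and \code{per_codon_mean}.
#' @export
insertCodonScan <- function(model, ts, codons = NULL, bins = 50L,
                            species = "human", ...) {
  all_codons <- apply(expand.grid(.BASES, .BASES, .BASES)[, 3:1], 1,
                      paste0, collapse = "")
  all_codons <- setdiff(all_codons, .STOP_CODONS)
  if (is.null(codons)) codons <- all_codons
  profile <- matrix(NA_real_, length(codons), bins,
                    dimnames = list(codons, NULL))
  for (cd in codons) {
    cb <- strsplit(cd, "")[[1]]
    mutate <- function(tensor, anchor_enc, tm, anchor_tx) {
      ## snap to the first in-frame codon start at or after the anchor
      phase <- (anchor_tx - tm$utr5_len - 1L) %% 3L
      shift <- if (phase == 0L) 0L else 3L - phase
      a_tx <- anchor_tx + shift
      if (a_tx + 2L > tm$utr5_len + tm$orf_len - 3L) return(NULL) # keep stop
      a_enc <- anchor_enc + shift
      if (a_enc < 1L) return(NULL)
      .mutateTensor(tensor, a_enc:(a_enc + 2L), cb)
    }
    sc <- .insertionScan(model, ts, species, regions = "orf", bins = bins,
                         span = 3L, mutate = mutate, ...)
    profile[cd, ] <- sc$mean_delta["orf", ]
  }
  list(profile = profile,
       per_codon_mean = rowMeans(profile, na.rm = TRUE))
}

#' Predicted effect of transcript-level variants
#'
#' Delta = prediction(alt) - prediction(ref), with the external-mode
#' ensemble when an ensemble is supplied. The reference allele must match
#' the transcript sequence at the stated position.
#'
#' @param model Model or ensemble.
#' @param ts A \linkS4class{TranscriptSet}.
#' @param variants \code{data.frame} with columns \code{transcript_id},
#'   \code{pos} (0-based spliced coordinate), \code{ref}, \code{alt}.
#' @param species Head to use.
#' @return The input with a \code{delta} column appended.
#' @export
variantEffect <- function(model, ts, variants, species = "human") {
  stopifnot(all(c("transcript_id", "pos", "ref", "alt") %in%
                colnames(variants)))
  hyper <- if (is(model, "SalukiEnsemble")) model@members[[1]]@hyper
           else model@hyper
  predict_ <- .tensorPredictor(model, species)
  variants$delta <- NA_real_
  for (tx in unique(variants$transcript_id)) {
    tm <- transcriptModel(ts, tx)
    rows <- which(variants$transcript_id == tx)
    seqc <- strsplit(chartr("T", "U", toupper(tm$seq)), "")[[1]]
    obs <- seqc[variants$pos[rows] + 1L]
    want <- chartr("T", "U", toupper(variants$ref[rows]))
    if (any(obs != want)) {
      bad <- rows[obs != want][1]
      stop(sprintf(
        "ref mismatch for %s at pos %d: variant says %s, transcript has %s",
        tx, variants$pos[bad], variants$ref[bad],
        seqc[variants$pos[bad] + 1L]))
    }
    enc <- encodeMrna(tm$seq, tm$utr5_len, tm$orf_len, tm$junctions,
                      hyper$L_max)
    offset <- max(0L, nchar(tm$seq) - hyper$L_max)
    ref_pred <- predict_(list(enc$tensor))
    enc_pos <- variants$pos[rows] + 1L - offset
    if (any(enc_pos < 1L))
      stop("variant position lies in the truncated 5' portion")
    tensors <- lapply(seq_along(rows), function(q)
      .mutateTensor(enc$tensor, enc_pos[q],
                    chartr("T", "U", toupper(variants$alt[rows[q]]))))
    variants$delta[rows] <- predict_(tensors) - ref_pred
  }
  variants
}

#' Reporter scaffold constructor
#'
#' Describes the reporter construct context into which fragments are
#' integrated: 5'UTR/ORF sequence and an insertion site inside the 3'UTR.
#'
#' @param seq Scaffold transcript sequence (A/C/G/U or T).
#' @param utr5_len,orf_len Region lengths.
#' @param insertion_site 0-based transcript coordinate of the insertion
#'   point; must lie within the 3'UTR.
#' @param junctions 0-based junction positions.
#' @return List of class \code{"reporter_scaffold"}.
#' @export
reporterScaffold <- function(seq, utr5_len, orf_len, insertion_site,
                             junctions = integer()) {
  seq <- chartr("Tt", "Uu", seq)
  if (is.null(insertion_site) || is.na(insertion_site))
    stop("scaffold missing insertion site")
  if (insertion_site < utr5_len + orf_len || insertion_site > nchar(seq))
    stop("insertion site must lie within the 3'UTR")
  structure(list(seq = seq, utr5_len = as.integer(utr5_len),
                 orf_len = as.integer(orf_len),
                 insertion_site = as.integer(insertion_site),
                 junctions = as.integer(junctions)),
            class = "reporter_scaffold")
}

#' A synthetic default reporter scaffold
#'
#' A seeded random construct (70-nt 5'UTR, 720-nt ORF, 400-nt 3'UTR with
#' the insertion site at its midpoint) standing in for a proprietary
#' reporter vector; clearly synthetic, for demonstrations and tests.
#'
#' @param seed Integer seed.
#' @return A \code{\link{reporterScaffold}}.
#' @export
syntheticReporterScaffold <- function(seed = 1L) {
  .withSeed(seed, {
    rseq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")
    orf_core <- rseq(714)
    seq <- paste0(rseq(70), "AUG", orf_core, "UAA", rseq(400))
    reporterScaffold(seq, 70L, 720L, insertion_site = 70L + 720L + 200L)
  })
}

#' Score a fragment in a reporter construct
#'
#' Builds the chimeric transcript (scaffold with the fragment spliced into
#' its 3'UTR at the declared site), encodes it with the scaffold's codon
#' and splice tracks, and predicts its half-life. With two fragments the
#' per-variant delta equals the variant effect computed on the chimera.
#'
#' @param model Model or ensemble.
#' @param scaffold A \code{\link{reporterScaffold}}.
#' @param fragment RNA string inserted into the 3'UTR (may be empty, which
#'   returns the scaffold baseline).
#' @param species Head to use.
#' @return Scalar prediction.
#' @export
reporterEffect <- function(model, scaffold, fragment, species = "human") {
  stopifnot(inherits(scaffold, "reporter_scaffold"))
  hyper <- if (is(model, "SalukiEnsemble")) model@members[[1]]@hyper
           else model@hyper
  fragment <- chartr("Tt", "Uu", fragment)
  s <- scaffold$insertion_site
  chim <- paste0(substr(scaffold$seq, 1, s), fragment,
                 substr(scaffold$seq, s + 1, nchar(scaffold$seq)))
  jx <- scaffold$junctions
  jx <- ifelse(jx > s, jx + nchar(fragment), jx)
  enc <- encodeMrna(chim, scaffold$utr5_len, scaffold$orf_len, jx,
                    hyper$L_max)
  .tensorPredictor(model, species)(list(enc$tensor))
}

## Midrank AUROC of scores for a positive/negative labelling.
.aucMidrank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Matched variant-set benchmark
#'
#' Positives are fine-mapped variants with PIP above \code{pip_hi}; each
#' is matched (without replacement) to a negative with PIP below
#' \code{pip_lo} from the same transcript region but a different gene,
#' with the closest gene-expression value. The AUROC of the absolute
#' predicted effect ranking is computed with the midrank convention.
#'
#' @param variants \code{data.frame} with columns \code{gene},
#'   \code{region}, \code{pip}, \code{expression}, and \code{score} (the
#'   absolute predicted half-life difference).
#' @param pip_hi,pip_lo PIP thresholds (0.9 / 0.01).
#' @return List with \code{pairs} (positive/negative index table),
#'   \code{auroc}, and the score vectors.
#' @export
matchedVariantBenchmark <- function(variants, pip_hi = 0.9,
                                    pip_lo = 0.01) {
  stopifnot(all(c("gene", "region", "pip", "expression", "score") %in%
                colnames(variants)))
  pos <- which(variants$pip > pip_hi)
  if (!length(pos)) stop("no positive variants at PIP > ", pip_hi)
  cand <- which(variants$pip < pip_lo)
  used <- logical(nrow(variants))
  neg <- integer(length(pos))
  unmatched <- character()
  for (q in seq_along(pos)) {
    i <- pos[q]
    ok <- cand[!used[cand] &
                 variants$region[cand] == variants$region[i] &
                 variants$gene[cand] != variants$gene[i]]
    if (!length(ok)) {
      unmatched <- c(unmatched, rownames(variants)[i])
      next
    }
    j <- ok[which.min(abs(variants$expression[ok] -
                            variants$expression[i]))]
    neg[q] <- j
    used[j] <- TRUE
  }
  if (length(unmatched))
    stop("insufficient negatives for positive(s): ",
         paste(unmatched, collapse = ", "))
  list(pairs = data.frame(positive = pos, negative = neg),
       auroc = .aucMidrank(variants$score[pos], variants$score[neg]),
       positive_scores = variants$score[pos],
       negative_scores = variants$score[neg])
}
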