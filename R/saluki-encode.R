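## 6-track encoding of mRNAs and the homology-aware fold assignment.

.NT_CHANNELS <- c(A = 1L, C = 2L, G = 3L, U = 4L)

#' Encode one mRNA as an L_max x 6 tensor
#'
#' Channels 1-4 one-hot encode A, C, G, U (T is accepted and mapped to U;
#' N gives an all-zero nucleotide column). Channel 5 marks the 5'-most
#' nucleotide of every non-first exon (the exon junctions); channel 6
#' marks the first nucleotide of every codon, which implicitly delimits
#' the UTRs. Sequences longer than \code{L_max} keep their 3'-most
#' \code{L_max} nt (track coordinates shifted accordingly); shorter ones
#' are zero-padded at the 3' end.
#'
#' @param seq Character scalar over A/C/G/U/T/N.
#' @param utr5_len,orf_len Region lengths in nt (the codon track spans
#'   \code{utr5_len + 1 .. utr5_len + orf_len}).
#' @param junctions Integer vector of 0-based junction positions on the
#'   spliced sequence.
#' @param L_max Tensor width.
#' @return List with \code{tensor} (\code{L_max} x 6 matrix) and
#'   \code{true_length}.
#' @export
encodeMrna <- function(seq, utr5_len, orf_len, junctions = integer(),
                       L_max = 12288L) {
  seq <- chartr("tT", "uU", seq)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- !chars %in% c("A", "C", "G", "U", "N")
  if (any(bad))
    stop("invalid character(s) in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  len <- length(chars)
  offset <- max(0L, len - L_max)          # 5' truncation for long mRNAs
  kept <- chars[(offset + 1L):len]
  tl <- length(kept)
  tensor <- matrix(0, L_max, 6L)
  ch <- .NT_CHANNELS[kept]
  hit <- which(!is.na(ch))
  tensor[cbind(hit, ch[hit])] <- 1
  jpos <- junctions + 1L - offset         # 1-based, shifted by truncation
  jpos <- jpos[jpos >= 1L & jpos <= tl]
  tensor[jpos, 5L] <- 1
  if (orf_len > 0L) {
    cstart <- seq.int(utr5_len + 1L, utr5_len + orf_len, by = 3L) - offset
    cstart <- cstart[cstart >= 1L & cstart <= tl]
    tensor[cstart, 6L] <- 1
  }
  list(tensor = tensor, true_length = tl)
}

#' Encode a TranscriptSet
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param L_max Tensor width (12,288 at full scale).
#' @param species Species tag, recycled over transcripts.
#' @return An \linkS4class{EncodedRNASet}.
#' @export
encodeTranscripts <- function(ts, L_max = 12288L, species = "human") {
  lens <- regionLengths(ts)
  seqs <- as.character(splicedSeq(ts))
  enc <- lapply(seq_len(length(ts)), function(i)
    encodeMrna(seqs[i], lens[i, "utr5"], lens[i, "orf"],
               as.integer(ts@junctions[[i]]), L_max))
  new("EncodedRNASet",
      tensors = lapply(enc, `[[`, "tensor"),
      trueLength = vapply(enc, `[[`, integer(1), "true_length"),
      species = rep_len(species, length(ts)),
      geneId = geneIds(ts), Lmax = as.integer(L_max))
}

#' Homology-aware cross-validation folds for two species
#'
#' Human genes are randomly partitioned into balanced folds; every mouse
#' gene with a mapped one-to-one human ortholog inherits its ortholog's
#' fold (so homologs never straddle a train/test split); unmapped mouse
#' genes are assigned to balance fold sizes.
#'
#' @param human_genes,mouse_genes Character vectors of gene IDs.
#' @param ortholog_map \code{data.frame} with columns \code{human},
#'   \code{mouse} (one-to-one where present), or \code{NULL}.
#' @param n_folds Number of folds (10).
#' @param seed Integer seed.
#' @return List with named integer vectors \code{human} and \code{mouse}.
#' @export
assignHomologyFolds <- function(human_genes, mouse_genes,
                                ortholog_map = NULL, n_folds = 10L,
                                seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  seeds <- .childSeeds(seed, 2L)
  hf <- .withSeed(seeds[1],
                  sample(rep_len(seq_len(n_folds), length(human_genes))))
  names(hf) <- human_genes
  mf <- stats::setNames(rep(NA_integer_, length(mouse_genes)), mouse_genes)
  if (!is.null(ortholog_map)) {
    om <- ortholog_map[ortholog_map$human %in% human_genes &
                         ortholog_map$mouse %in% mouse_genes, , drop = FALSE]
    if (anyDuplicated(om$human) || anyDuplicated(om$mouse))
      stop("ortholog map must be one-to-one")
    mf[om$mouse] <- hf[om$human]
  }
  un <- which(is.na(mf))
  if (length(un)) {
    counts <- tabulate(mf[!is.na(mf)], n_folds)
    un <- .withSeed(seeds[2], sample(un))
    for (i in un) {
      k <- which.min(counts)
      mf[i] <- k
      counts[k] <- counts[k] + 1L
    }
  }
  list(human = hf, mouse = mf)
}
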