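#' Accessors for package classes
#'
#' Small accessor family: slot access for user code goes through these.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors The gene-by-sample value matrix of a
#'   \linkS4class{HalfLifeMatrix}.
#' @export
hlValues <- function(x) SummarizedExperiment::assay(x, "halflife")

#' @describeIn accessors The processing stage tag.
#' @export
hlStage <- function(x) x@stage

#' @describeIn accessors Per-sample metadata as a \code{data.frame}.
#' @export
sampleMeta <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn accessors Named PC1 scores of a
#'   \linkS4class{ConsensusHalfLife}.
#' @export
geneScores <- function(x) x@geneScores

#' @describeIn accessors Per-PC variance fractions.
#' @export
varianceExplained <- function(x) x@varianceExplained

#' @describeIn accessors Gene-by-feature matrix of a
#'   \linkS4class{FeatureTable}.
#' @export
featureValues <- function(x) x@values

#' @describeIn accessors Feature group letters (one per column).
#' @export
featureGroups <- function(x) x@groups

#' @describeIn accessors Spliced sequences of a \linkS4class{TranscriptSet}.
#' @export
splicedSeq <- function(x) x@seq

#' @describeIn accessors Transcript IDs of a \linkS4class{TranscriptSet}.
#' @export
transcriptIds <- function(x) names(x@seq)

#' @describeIn accessors Gene IDs of a \linkS4class{TranscriptSet}.
#' @export
geneIds <- function(x) x@geneId

#' @describeIn accessors Region lengths of a \linkS4class{TranscriptSet} as
#'   a three-column matrix (utr5, orf, utr3).
#' @export
regionLengths <- function(x)
  cbind(utr5 = x@utr5Len, orf = x@orfLen, utr3 = x@utr3Len)

#' @describeIn accessors Exon-junction positions (0-based, spliced
#'   coordinates) as an \code{IntegerList}.
#' @export
exonJunctions <- function(x) x@junctions

#' Subset a TranscriptSet
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @param i Index vector (numeric, logical, or transcript IDs).
#' @param j,... ,drop Ignored.
#' @return A \linkS4class{TranscriptSet}.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seq))
  new("TranscriptSet", seq = x@seq[i], geneId = x@geneId[i],
      utr5Len = x@utr5Len[i], orfLen = x@orfLen[i], utr3Len = x@utr3Len[i],
      intronLenTotal = x@intronLenTotal[i], junctions = x@junctions[i])
})

#' Number of transcripts in a TranscriptSet
#' @param x A \linkS4class{TranscriptSet}.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@seq))

#' Extract one transcript as a plain list
#'
#' Convenience view of a single representative transcript: sequence string,
#' gene/transcript IDs, region lengths, junction positions, intron total.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @param i Single index or transcript ID.
#' @return Named list.
#' @export
transcriptModel <- function(x, i) {
  if (is.character(i)) i <- match(i, names(x@seq))
  stopifnot(length(i) == 1L, !is.na(i))
  list(transcript_id = names(x@seq)[i], gene_id = x@geneId[i],
       seq = as.character(x@seq[[i]]),
       utr5_len = x@utr5Len[i], orf_len = x@orfLen[i],
       utr3_len = x@utr3Len[i],
       junctions = as.integer(x@junctions[[i]]),
       intron_len_total = x@intronLenTotal[i])
}
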