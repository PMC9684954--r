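#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom IRanges IntegerList
#' @importFrom IRanges IntegerList
NULL

## ---- stage machinery -------------------------------------------------------

.HL_STAGES <- c("raw", "transformed", "filtered", "standardized",
                "imputed", "normalized")

.stageRank <- function(stage) match(stage, .HL_STAGES)

## Method -> method class mapping. Pulse-labeling protocols tag nascent RNA
## with modified nucleosides; shutoff protocols block transcription and watch
## decay. The class is a deterministic function of the method string.
.PULSE_PATTERNS   <- c("4sU", "BrU", "5EU", "BrU4sU", "SLAM", "TimeLapse",
                       "TT-seq", "TUC")
.SHUTOFF_PATTERNS <- c("ActD", "Amanitin", "DRB", "Triptolide")

#' Classify a half-life measurement method
#'
#' Maps a free-text measurement method (e.g. \code{"4sU"}, \code{"ActD"},
#' \code{"BrU (BRIC-seq)"}) to one of the two methodological classes whose
#' systematic disagreement the compendium pipeline quantifies.
#'
#' @param method Character vector of method descriptions.
#' @return Character vector, each element \code{"pulse_labeling"} or
#'   \code{"transcriptional_shutoff"}.
#' @examples
#' methodClass(c("4sU", "ActD", "BrU (BRIC-seq)"))
#' @export
methodClass <- function(method) {
  pulse <- grepl(paste(.PULSE_PATTERNS, collapse = "|"), method,
                 ignore.case = TRUE)
  shut  <- grepl(paste(.SHUTOFF_PATTERNS, collapse = "|"), method,
                 ignore.case = TRUE)
  if (any(pulse & shut))
    stop("ambiguous method description(s): ",
         paste(method[pulse & shut], collapse = ", "))
  if (any(!pulse & !shut))
    stop("unrecognized method description(s): ",
         paste(unique(method[!pulse & !shut]), collapse = ", "))
  ifelse(pulse, "pulse_labeling", "transcriptional_shutoff")
}

## ---- HalfLifeMatrix --------------------------------------------------------

#' HalfLifeMatrix: a gene-by-sample half-life matrix with processing stage
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are genes, columns are
#' samples; the single assay \code{"halflife"} holds (possibly sparse, with
#' \code{NA} for missing) half-life values on the scale implied by the
#' processing \code{stage}. Column metadata carries the per-sample
#' description (study, species, cell type, method, method class, unit,
#' degradation-rate flag). The stage advances monotonically through
#' \code{raw}, \code{transformed}, \code{filtered}, \code{standardized},
#' \code{imputed}, \code{normalized}; from \code{imputed} onward no missing
#' values remain.
#'
#' @slot stage Character scalar, one of the six processing stages.
#' @export
setClass("HalfLifeMatrix",
         contains = "SummarizedExperiment",
         representation(stage = "character"))

setValidity("HalfLifeMatrix", function(object) {
  msg <- NULL
  if (length(object@stage) != 1L || !object@stage %in% .HL_STAGES)
    msg <- c(msg, paste0("stage must be one of: ",
                         paste(.HL_STAGES, collapse = ", ")))
  else {
    x <- SummarizedExperiment::assay(object, "halflife")
    if (.stageRank(object@stage) >= .stageRank("imputed") && anyNA(x))
      msg <- c(msg, "missing values present at stage >= imputed")
    if (object@stage == "standardized") {
      mu <- apply(x, 2, function(v) mean(v[!is.na(v)]))
      sdv <- apply(x, 2, function(v) stats::sd(v[!is.na(v)]))
      if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8))
        msg <- c(msg, "standardized columns must have observed mean 0, sd 1")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "study", "species", "cell_type", "method",
            "method_class", "unit", "is_degradation_rate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks columns: ",
                         paste(miss, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a HalfLifeMatrix
#'
#' @param values Numeric gene-by-sample matrix with rownames (gene IDs) and
#'   colnames (sample IDs); \code{NA} marks missing measurements.
#' @param meta \code{data.frame} of per-sample metadata with columns
#'   \code{sample_id}, \code{study}, \code{species}, \code{cell_type},
#'   \code{method}, \code{unit} (\code{"hours"}, \code{"minutes"}, or
#'   \code{NA} for degradation-rate samples) and
#'   \code{is_degradation_rate} (logical). \code{method_class} is derived
#'   with \code{\link{methodClass}} if absent.
#' @param stage Processing stage tag (see class documentation).
#' @return A \linkS4class{HalfLifeMatrix}.
#' @examples
#' m <- matrix(rlnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' meta <- data.frame(sample_id = paste0("s", 1:3), study = "A",
#'                    species = "human", cell_type = "HeLa",
#'                    method = c("4sU", "ActD", "4sU"),
#'                    unit = "hours", is_degradation_rate = FALSE)
#' HalfLifeMatrix(m, meta)
#' @export
HalfLifeMatrix <- function(values, meta, stage = "raw") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  meta <- as.data.frame(meta)
  if (!"method_class" %in% colnames(meta))
    meta$method_class <- methodClass(meta$method)
  if (!"unit" %in% colnames(meta)) meta$unit <- NA_character_
  if (!"is_degradation_rate" %in% colnames(meta))
    meta$is_degradation_rate <- FALSE
  bad <- !meta$is_degradation_rate & is.na(meta$unit)
  if (any(bad))
    stop("unit required for half-life samples: ",
         paste(meta$sample_id[bad], collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing for some samples in 'values'")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(halflife = values),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
  new("HalfLifeMatrix", se, stage = stage)
}

## ---- ConsensusHalfLife -----------------------------------------------------

#' ConsensusHalfLife: per-gene consensus half-life scores
#'
#' Holds the first-principal-component scores of a processed gene-by-sample
#' half-life matrix (the consensus, cell-type-agnostic half-life phenotype),
#' the per-component variance fractions, and a description of the sign
#' anchoring applied (PC orientation is arbitrary; scores are oriented to
#' correlate positively with per-gene means so larger means longer-lived).
#'
#' @slot geneScores Named numeric vector of PC1 scores.
#' @slot varianceExplained Numeric vector of per-PC variance fractions.
#' @slot signAnchor Character scalar describing the orientation rule.
#' @export
setClass("ConsensusHalfLife",
         representation(geneScores = "numeric",
                        varianceExplained = "numeric",
                        signAnchor = "character"))

setValidity("ConsensusHalfLife", function(object) {
  msg <- NULL
  if (is.null(names(object@geneScores)))
    msg <- c(msg, "geneScores must be named by gene ID")
  ve <- object@varianceExplained
  if (any(ve < -1e-8) || sum(ve) > 1 + 1e-8)
    msg <- c(msg, "variance fractions must be in [0,1] and sum to <= 1")
  if (is.null(msg)) TRUE else msg
})

## ---- TranscriptSet ---------------------------------------------------------

#' TranscriptSet: representative transcript models
#'
#' One representative transcript per gene: the spliced mRNA sequence
#' (RNA alphabet, 5' to 3'), the 5'UTR/ORF/3'UTR partition of its length,
#' the exon-junction positions on the spliced sequence (0-based; each value
#' is the position of the first nucleotide of a downstream exon), and the
#' total intron length removed by splicing.
#'
#' @slot seq \linkS4class{RNAStringSet}, names are transcript IDs.
#' @slot geneId Character vector of gene IDs (parallel to \code{seq}).
#' @slot utr5Len,orfLen,utr3Len,intronLenTotal Integer vectors.
#' @slot junctions \linkS4class{IntegerList} of spliced-coordinate junction
#'   positions.
#' @export
setClass("TranscriptSet",
         representation(seq = "RNAStringSet",
                        geneId = "character",
                        utr5Len = "integer",
                        orfLen = "integer",
                        utr3Len = "integer",
                        intronLenTotal = "integer",
                        junctions = "IntegerList"))

setValidity("TranscriptSet", function(object) {
  msg <- NULL
  n <- length(object@seq)
  lens <- Biostrings::width(object@seq)
  if (length(object@geneId) != n || length(object@utr5Len) != n ||
      length(object@orfLen) != n || length(object@utr3Len) != n ||
      length(object@intronLenTotal) != n || length(object@junctions) != n)
    msg <- c(msg, "slot lengths disagree")
  else {
    if (any(object@utr5Len + object@orfLen + object@utr3Len != lens))
      msg <- c(msg, "region lengths must partition the spliced sequence")
    if (any(object@orfLen %% 3L != 0L) || any(object@orfLen < 3L))
      msg <- c(msg, "ORF length must be a positive multiple of 3")
    jmin <- vapply(object@junctions, function(j)
      if (length(j)) min(j) else 1L, integer(1))
    jmax <- vapply(object@junctions, function(j)
      if (length(j)) max(j) else 1L, integer(1))
    if (any(jmin <= 0L) || any(jmax >= lens))
      msg <- c(msg, "junction positions must lie strictly inside (0, length)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a TranscriptSet
#'
#' @param seq \linkS4class{RNAStringSet} (or named character vector over
#'   A/C/G/U, T accepted and mapped to U) of spliced sequences, named by
#'   transcript ID.
#' @param geneId Character vector of gene IDs.
#' @param utr5Len,orfLen,utr3Len Region lengths in nt.
#' @param junctions List (or \code{IntegerList}) of 0-based junction
#'   positions on the spliced sequence; empty for single-exon transcripts.
#' @param intronLenTotal Total intron length per transcript (nt).
#' @return A \linkS4class{TranscriptSet}.
#' @export
TranscriptSet <- function(seq, geneId, utr5Len, orfLen, utr3Len,
                          junctions = vector("list", length(geneId)),
                          intronLenTotal = integer(length(geneId))) {
  if (is.character(seq))
    seq <- Biostrings::RNAStringSet(chartr("Tt", "Uu", seq))
  new("TranscriptSet", seq = seq, geneId = as.character(geneId),
      utr5Len = as.integer(utr5Len), orfLen = as.integer(orfLen),
      utr3Len = as.integer(utr3Len),
      intronLenTotal = as.integer(intronLenTotal),
      junctions = IRanges::IntegerList(junctions))
}

## ---- FeatureTable ----------------------------------------------------------

.GROUP_ALPHABET <- c("B", "C", "5", "O", "3", "M", "S", "D",
                     "E", "e", "m", "P", "R")

#' FeatureTable: gene-by-feature matrix with feature groups
#'
#' Every feature belongs to exactly one named group from the single-letter
#' alphabet used to assemble model codes (e.g. \code{"BC3MS"}): B basic mRNA
#' properties, C codon frequencies, 5/O/3 k-mer frequencies of the 5'UTR,
#' ORF and 3'UTR, M microRNA repression scores, S/D windowed RBP-binding
#' scores from two external predictors, E/e/m CLIP, eCLIP and m6A-pathway
#' peak counts, P PAR-CLIP peak counts, R RIP-seq and translational
#' efficiency measurements.
#'
#' @slot values Numeric gene-by-feature matrix.
#' @slot groups Character vector, one group letter per feature column.
#' @export
setClass("FeatureTable",
         representation(values = "matrix", groups = "character"))

setValidity("FeatureTable", function(object) {
  msg <- NULL
  if (ncol(object@values) != length(object@groups))
    msg <- c(msg, "one group letter per feature column required")
  if (!all(object@groups %in% .GROUP_ALPHABET))
    msg <- c(msg, paste0("groups must be in {",
                         paste(.GROUP_ALPHABET, collapse = ","), "}"))
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msg <- c(msg, "values must have gene rownames and feature colnames")
  if (anyDuplicated(colnames(object@values)))
    msg <- c(msg, "duplicate feature names")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FeatureTable
#'
#' @param values Numeric gene-by-feature matrix (gene rownames, feature
#'   colnames).
#' @param groups Character vector of group letters, one per column.
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(values, groups) {
  new("FeatureTable", values = values, groups = as.character(groups))
}

## ---- EncodedRNASet ---------------------------------------------------------

#' EncodedRNASet: fixed-width 6-track mRNA encodings
#'
#' Each mRNA is encoded as an \code{L_max x 6} matrix: four one-hot
#' nucleotide channels (A, C, G, U), a splice track marking the 5'-most
#' nucleotide of every non-first exon, and a codon-frame track marking the
#' first nucleotide of every codon. Sequences longer than \code{L_max} keep
#' their 3'-most \code{L_max} nt; shorter ones are zero-padded at the 3'
#' end. \code{trueLength} records the pre-padding length.
#'
#' @slot tensors List of \code{L_max x 6} numeric matrices.
#' @slot trueLength Integer vector of encoded (pre-padding) lengths.
#' @slot species Character vector (\code{"human"}/\code{"mouse"}).
#' @slot geneId Character vector of gene IDs.
#' @slot Lmax Integer scalar, the fixed tensor width.
#' @export
setClass("EncodedRNASet",
         representation(tensors = "list", trueLength = "integer",
                        species = "character", geneId = "character",
                        Lmax = "integer"))

setValidity("EncodedRNASet", function(object) {
  n <- length(object@tensors)
  if (length(object@trueLength) != n || length(object@geneId) != n ||
      length(object@species) != n)
    return("slot lengths disagree")
  ok <- vapply(object@tensors, function(m)
    is.matrix(m) && nrow(m) == object@Lmax && ncol(m) == 6L, logical(1))
  if (!all(ok)) return("all tensors must be Lmax x 6 matrices")
  if (any(object@trueLength > object@Lmax))
    return("trueLength may not exceed Lmax")
  TRUE
})

## ---- SalukiModel and SalukiEnsemble ----------------------------------------

#' SalukiModel: one trained (or initialized) network parameter set
#'
#' A hybrid convolutional/recurrent half-life regressor: a tower of
#' convolution blocks pooling the input down to coarse resolution, a
#' backward gated recurrent unit aggregating the variable-length sequence
#' from the padded 3' end to the 5' end, a shared dense block, and one
#' output head per species.
#'
#' @slot params Named list of parameter arrays.
#' @slot hyper Named list of hyperparameters (see
#'   \code{\link{salukiHyperparams}}).
#' @slot bnStats Named list of batch-norm running statistics for inference.
#' @slot log Training log (per-epoch validation correlations), possibly
#'   empty.
#' @export
setClass("SalukiModel",
         representation(params = "list", hyper = "list",
                        bnStats = "list", log = "list"))

#' SalukiEnsemble: fold-by-replicate collection of trained models
#'
#' @slot members List of \linkS4class{SalukiModel}s.
#' @slot fold Integer vector: held-out test fold of each member.
#' @slot replicate Integer vector: replicate index of each member.
#' @slot folds Named list of per-species named fold assignments.
#' @slot validationR Numeric vector of best validation correlations.
#' @export
setClass("SalukiEnsemble",
         representation(members = "list", fold = "integer",
                        replicate = "integer", folds = "list",
                        validationR = "numeric"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "HalfLifeMatrix", function(object) {
  x <- SummarizedExperiment::assay(object, "halflife")
  cat("HalfLifeMatrix:", nrow(x), "genes x", ncol(x), "samples",
      sprintf("[stage: %s]\n", object@stage))
  cat(sprintf("  missing: %.1f%%  species: %s\n",
              100 * mean(is.na(x)),
              paste(unique(object$species), collapse = ", ")))
})

setMethod("show", "ConsensusHalfLife", function(object) {
  cat("ConsensusHalfLife:", length(object@geneScores), "genes;",
      sprintf("PC1 explains %.1f%% of variance\n",
              100 * object@varianceExplained[1]))
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet:", length(object@seq), "transcripts;",
      "median length", stats::median(Biostrings::width(object@seq)), "nt\n")
})

setMethod("show", "FeatureTable", function(object) {
  tab <- table(object@groups)
  cat("FeatureTable:", nrow(object@values), "genes x",
      ncol(object@values), "features\n  groups:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "EncodedRNASet", function(object) {
  cat("EncodedRNASet:", length(object@tensors), "mRNAs, Lmax =",
      object@Lmax, "\n")
})

setMethod("show", "SalukiModel", function(object) {
  cat("SalukiModel:", salukiParamCount(object), "trainable parameters",
      sprintf("(%d channels, %d conv blocks)\n",
              object@hyper$channels, object@hyper$n_blocks))
})

setMethod("show", "SalukiEnsemble", function(object) {
  cat("SalukiEnsemble:", length(object@members), "members (",
      length(unique(object@fold)), "folds x",
      length(unique(object@replicate)), "replicates )\n")
})
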