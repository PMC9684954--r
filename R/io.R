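## TSV interfaces: sparse half-life matrices (gene rows, sample columns,
## empty cells = missing), sample metadata sheets, consensus tables, and
## feature tables with a sidecar group manifest.

#' Read a sparse half-life matrix and its metadata sheet
#'
#' @param matrix_path TSV with a \code{gene_id} column and one column per
#'   sample; empty cells (or NA) are missing.
#' @param meta_path TSV of per-sample metadata (see
#'   \code{\link{HalfLifeMatrix}}).
#' @param stage Stage tag of the stored matrix.
#' @return A \linkS4class{HalfLifeMatrix}.
#' @export
readHalfLifeMatrix <- function(matrix_path, meta_path, stage = "raw") {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(colnames(df)[1] == "gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  HalfLifeMatrix(m, meta, stage = stage)
}

#' Write a half-life matrix as TSV
#'
#' @param m A \linkS4class{HalfLifeMatrix}.
#' @param path Output TSV path (gene rows, sample columns; NA written as
#'   empty cells).
#' @export
writeHalfLifeMatrix <- function(m, path) {
  x <- hlValues(m)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a consensus table
#'
#' @param consensus A \linkS4class{ConsensusHalfLife}.
#' @param path Output TSV (columns gene_id, pc1_score).
#' @export
writeConsensus <- function(consensus, path) {
  utils::write.table(
    data.frame(gene_id = names(geneScores(consensus)),
               pc1_score = as.numeric(geneScores(consensus))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consensus table
#'
#' @param path TSV with columns gene_id, pc1_score.
#' @return Named numeric vector.
#' @export
readConsensus <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$pc1_score, df$gene_id)
}

#' Write a FeatureTable with its group manifest
#'
#' @param f A \linkS4class{FeatureTable}.
#' @param path Values TSV path; the manifest (feature, group) is written
#'   alongside as \code{<path>.groups.tsv}.
#' @export
writeFeatureTable <- function(f, path) {
  x <- featureValues(f)
  utils::write.table(data.frame(gene_id = rownames(x), x,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(feature = colnames(x),
                                group = featureGroups(f)),
                     paste0(path, ".groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FeatureTable written by \code{\link{writeFeatureTable}}
#'
#' @param path Values TSV path (with sidecar \code{<path>.groups.tsv}).
#' @return A \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  mode(x) <- "numeric"
  rownames(x) <- df$gene_id
  man <- utils::read.delim(paste0(path, ".groups.tsv"),
                           stringsAsFactors = FALSE)
  FeatureTable(x, man$group[match(colnames(x), man$feature)])
}
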