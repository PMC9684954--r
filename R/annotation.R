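## Building representative transcript models from annotations.
## Internal coordinates are 0-based half-open on the spliced sequence,
## 5'->3' in mRNA sense; GTF input (1-based closed) is converted at
## ingestion and minus-strand genes are reverse-complemented.

#' Select one representative transcript per gene
#'
#' Lexicographic maximization on (ORF length, 5'UTR length, 3'UTR length);
#' residual ties are broken by the lexicographically smallest transcript ID
#' for reproducibility.
#'
#' @param stats A \code{data.frame} with columns \code{gene_id},
#'   \code{transcript_id}, \code{orf_len}, \code{utr5_len}, \code{utr3_len}.
#' @return Character vector of chosen transcript IDs, named by gene ID.
#' @examples
#' df <- data.frame(gene_id = "g", transcript_id = c("t1", "t2"),
#'                  orf_len = c(300, 300), utr5_len = c(10, 20),
#'                  utr3_len = c(50, 5))
#' selectRepresentativeTranscript(df)  # t2: equal ORFs, longer 5'UTR
#' @export
selectRepresentativeTranscript <- function(stats) {
  stopifnot(all(c("gene_id", "transcript_id", "orf_len", "utr5_len",
                  "utr3_len") %in% colnames(stats)))
  ## descending on the criteria, ascending on transcript_id for ties
  o <- order(stats$gene_id, -stats$orf_len, -stats$utr5_len,
             -stats$utr3_len, stats$transcript_id)
  s <- stats[o, ]
  first <- !duplicated(s$gene_id)
  stats::setNames(s$transcript_id[first], s$gene_id[first])
}

## Assemble per-transcript structural statistics from parsed GTF features.
.transcriptStats <- function(exons, cds) {
  ex_by_tx <- split(exons, exons$transcript_id)
  cds_by_tx <- split(cds, cds$transcript_id)
  ids <- intersect(names(ex_by_tx), names(cds_by_tx))
  res <- lapply(ids, function(tx) {
    ex <- ex_by_tx[[tx]]
    cd <- cds_by_tx[[tx]]
    strand <- as.character(BiocGenerics::strand(ex))[1]
    dec <- strand == "-"
    ex <- ex[order(BiocGenerics::start(ex), decreasing = dec)]
    w <- BiocGenerics::width(ex)
    total <- sum(w)
    ## map a genomic position to 0-based spliced coordinate
    spliced_pos <- function(gpos) {
      off <- 0L
      for (k in seq_along(ex)) {
        s <- BiocGenerics::start(ex)[k]; e <- BiocGenerics::end(ex)[k]
        if (gpos >= s && gpos <= e) {
          return(off + if (dec) e - gpos else gpos - s)
        }
        off <- off + w[k]
      }
      NA_integer_
    }
    cds_first <- if (dec) max(BiocGenerics::end(cd)) else
      min(BiocGenerics::start(cd))
    cds_last <- if (dec) min(BiocGenerics::start(cd)) else
      max(BiocGenerics::end(cd))
    u5 <- spliced_pos(cds_first)
    last_sp <- spliced_pos(cds_last)
    orf <- sum(BiocGenerics::width(cd))
    if (is.na(u5) || is.na(last_sp) || last_sp - u5 + 1L != orf)
      return(NULL)  # CDS not contained in the exon structure
    junctions <- if (length(ex) > 1) cumsum(w)[-length(w)] else integer()
    starts <- BiocGenerics::start(ex); ends <- BiocGenerics::end(ex)
    st_asc <- sort(starts); en_asc <- sort(ends)
    intron <- if (length(ex) > 1)
      sum(st_asc[-1] - en_asc[-length(en_asc)] - 1L)
    else 0L
    list(transcript_id = tx, gene_id = ex$gene_id[1],
         chrom = as.character(GenomicRanges::seqnames(ex))[1],
         strand = strand, utr5_len = u5, orf_len = orf,
         utr3_len = total - u5 - orf, junctions = as.integer(junctions),
         intron_len_total = as.integer(intron),
         exon_start = starts, exon_end = ends, dec = dec)
  })
  res[!vapply(res, is.null, logical(1))]
}

#' Read representative transcripts from a GTF and FASTA
#'
#' Parses an Ensembl-dialect GTF (exon and CDS features with
#' \code{gene_id}/\code{transcript_id} attributes; \code{stop_codon}
#' features, when present, are appended to the ORF), chooses one
#' representative transcript per gene by
#' \code{\link{selectRepresentativeTranscript}}, and extracts spliced
#' sequences from the FASTA. Works equally with a genome FASTA (chromosome
#' seqnames) or a transcript FASTA whose records are named by the GTF
#' seqnames. T is normalized to U; ambiguity codes other than N are
#' rejected. Genes without an annotated CDS, or whose ORF length is not a
#' positive multiple of 3, are skipped with a diagnostic.
#'
#' @param gtf Path to a GTF file.
#' @param fasta Path to a FASTA file.
#' @return A \linkS4class{TranscriptSet} with one transcript per gene.
#' @export
readTranscriptSet <- function(gtf, fasta) {
  gr <- rtracklayer::import(gtf)
  type <- as.character(gr$type)
  exons <- gr[type == "exon"]
  cds <- gr[type %in% c("CDS", "stop_codon")]
  if (length(cds) == 0L) stop("no CDS features in ", gtf)
  stats_list <- .transcriptStats(exons, cds)
  if (!length(stats_list)) stop("no usable coding transcripts in ", gtf)
  stats <- do.call(rbind, lapply(stats_list, function(s)
    data.frame(gene_id = s$gene_id, transcript_id = s$transcript_id,
               orf_len = s$orf_len, utr5_len = s$utr5_len,
               utr3_len = s$utr3_len)))
  bad <- stats$orf_len %% 3L != 0L | stats$orf_len < 3L
  if (any(bad)) {
    message(sum(bad), " transcript(s) skipped: ORF length not a positive ",
            "multiple of 3")
    stats <- stats[!bad, , drop = FALSE]
  }
  if (!nrow(stats)) stop("no transcripts passed the ORF checks")
  chosen <- selectRepresentativeTranscript(stats)
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  keep <- vapply(stats_list, function(s)
    s$transcript_id %in% chosen, logical(1))
  stats_list <- stats_list[keep]
  seqs <- character(length(stats_list))
  for (i in seq_along(stats_list)) {
    s <- stats_list[[i]]
    if (!s$chrom %in% names(genome))
      stop("sequence ", s$chrom, " absent from FASTA")
    chr <- genome[[s$chrom]]
    o <- order(s$exon_start)
    pieces <- vapply(o, function(k)
      as.character(Biostrings::subseq(chr, s$exon_start[k],
                                      s$exon_end[k])), character(1))
    sp <- Biostrings::DNAString(paste0(pieces, collapse = ""))
    if (s$dec) sp <- Biostrings::reverseComplement(sp)
    seqs[i] <- as.character(sp)
  }
  bad_alpha <- grepl("[^ACGTUN]", seqs)
  if (any(bad_alpha))
    stop("ambiguity codes other than N in transcript(s): ",
         paste(vapply(stats_list[bad_alpha], `[[`, "", "transcript_id"),
               collapse = ", "))
  ts <- TranscriptSet(
    seq = stats::setNames(seqs, vapply(stats_list, `[[`, "",
                                       "transcript_id")),
    geneId = vapply(stats_list, `[[`, "", "gene_id"),
    utr5Len = vapply(stats_list, function(s) s$utr5_len, integer(1)),
    orfLen = vapply(stats_list, function(s) s$orf_len, integer(1)),
    utr3Len = vapply(stats_list, function(s) s$utr3_len, integer(1)),
    junctions = lapply(stats_list, `[[`, "junctions"),
    intronLenTotal = vapply(stats_list, function(s) s$intron_len_total,
                            integer(1)))
  ts[order(geneIds(ts))]
}

#' Extract region sequences from a TranscriptSet
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param region \code{"utr5"}, \code{"orf"}, or \code{"utr3"}.
#' @return An \linkS4class{RNAStringSet} (zero-width for empty regions).
#' @export
regionSeq <- function(ts, region = c("utr5", "orf", "utr3")) {
  region <- match.arg(region)
  lens <- regionLengths(ts)
  start <- switch(region, utr5 = rep(1L, length(ts)),
                  orf = lens[, "utr5"] + 1L,
                  utr3 = lens[, "utr5"] + lens[, "orf"] + 1L)
  width <- lens[, region]
  Biostrings::subseq(splicedSeq(ts), start = start, width = width)
}
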