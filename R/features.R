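## Sequence-derived and biochemical feature extraction (the feature groups
## assembled into lasso model codes such as "BC3MS").

.STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Basic mRNA features
#'
#' Eight per-gene features: G/C content of the 5'UTR, ORF and 3'UTR;
#' log10(x + 0.1)-transformed lengths of the three regions and of the total
#' intron content; and ORF exon-junction density (junctions strictly inside
#' the ORF per kilobase of ORF sequence). The GC content of an empty region
#' is missing.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @return Numeric gene-by-8 matrix (rownames are gene IDs).
#' @export
basicFeatures <- function(ts) {
  lens <- regionLengths(ts)
  gc_one <- function(r) {
    s <- regionSeq(ts, r)
    w <- Biostrings::width(s)
    cnt <- Biostrings::letterFrequency(s, letters = c("G", "C"))
    out <- rowSums(cnt) / w
    out[w == 0L] <- NA_real_
    out
  }
  gc <- cbind(utr5 = gc_one("utr5"), orf = gc_one("orf"),
              utr3 = gc_one("utr3"))
  nj_orf <- vapply(seq_len(length(ts)), function(i) {
    j <- ts@junctions[[i]]
    sum(j > lens[i, "utr5"] & j < lens[i, "utr5"] + lens[i, "orf"])
  }, numeric(1))
  dens <- nj_orf / (lens[, "orf"] / 1000)
  out <- cbind(utr5_gc = gc[, "utr5"], orf_gc = gc[, "orf"],
               utr3_gc = gc[, "utr3"],
               utr5_len = log10(lens[, "utr5"] + 0.1),
               orf_len = log10(lens[, "orf"] + 0.1),
               utr3_len = log10(lens[, "utr3"] + 0.1),
               intron_len = log10(ts@intronLenTotal + 0.1),
               orf_junction_density = dens)
  rownames(out) <- geneIds(ts)
  out
}

#' Codon frequencies (61 non-stop codons)
#'
#' Non-overlapping codons over the ORF; counts are normalized by the total
#' codon count of the gene (including stop codons; codons containing N are
#' excluded from numerator and denominator), then the three stop codons are
#' dropped, leaving 61 features.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @return Numeric gene-by-61 matrix.
#' @export
codonFrequencies <- function(ts) {
  orf <- regionSeq(ts, "orf")
  cnt <- Biostrings::oligonucleotideFrequency(orf, width = 3, step = 3)
  tot <- rowSums(cnt)
  freq <- cnt / tot
  keep <- !colnames(freq) %in% .STOP_CODONS
  freq <- freq[, keep, drop = FALSE]
  colnames(freq) <- paste0("codon_", colnames(freq))
  rownames(freq) <- geneIds(ts)
  freq
}

#' K-mer frequencies for one functional region
#'
#' Overlapping k-mer counts for k = 1..7 over the chosen region, each k
#' normalized by the total count of that k (so each k is a proper frequency
#' distribution; windows containing N are excluded from numerator and
#' denominator). K-mers longer than the region count as 0. The
#' concatenation over k gives 4 + 16 + ... + 16384 = 21,844 features.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param region \code{"utr5"}, \code{"orf"}, or \code{"utr3"}.
#' @param k_range Integer vector of k values (default \code{1:7}).
#' @return Numeric gene-by-feature matrix; feature names are prefixed by
#'   the region.
#' @export
kmerFrequencies <- function(ts, region = c("utr5", "orf", "utr3"),
                            k_range = 1:7) {
  region <- match.arg(region)
  s <- regionSeq(ts, region)
  mats <- lapply(k_range, function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(s, width = k, step = 1)
    tot <- rowSums(cnt)
    freq <- cnt / ifelse(tot == 0, 1, tot)  # short/N-only regions -> 0
    freq
  })
  out <- do.call(cbind, mats)
  colnames(out) <- paste0(region, "_", colnames(out))
  rownames(out) <- geneIds(ts)
  out
}

#' Windowed external-predictor score averages
#'
#' Harness for per-region averaging of windowed sequence scores (the scheme
#' used to summarize external RBP-binding predictors): the region is tiled
#' in 50-nt windows, each window is padded with its neighboring transcript
#' sequence (or N beyond the transcript ends) to \code{window + 2*flank}
#' nt, the supplied predictor scores every padded window per factor, and
#' the per-factor sums are divided by the region length.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param region \code{"utr5"}, \code{"orf"}, or \code{"utr3"}.
#' @param predictor Function taking a character vector of equal-width
#'   padded windows and returning a numeric matrix (windows x factors,
#'   named columns).
#' @param window Window width in nt (50).
#' @param flank Padding on each side: 475 for the 1000-nt input mode, 50
#'   for the 150-nt mode.
#' @return Numeric gene-by-factor matrix; all-missing rows for regions
#'   shorter than 1 nt.
#' @export
windowAverageScores <- function(ts, region = c("utr5", "orf", "utr3"),
                                predictor, window = 50L, flank = 475L) {
  region <- match.arg(region)
  lens <- regionLengths(ts)
  offset <- switch(region, utr5 = rep(0L, length(ts)),
                   orf = lens[, "utr5"],
                   utr3 = lens[, "utr5"] + lens[, "orf"])
  full <- as.character(splicedSeq(ts))
  rows <- vector("list", length(ts))
  for (i in seq_len(length(ts))) {
    rl <- lens[i, region]
    if (rl < 1L) { rows[[i]] <- NULL; next }
    tx <- full[i]
    L <- nchar(tx)
    starts <- seq(1L, rl, by = window)           # region-relative
    wins <- vapply(starts, function(a) {
      t0 <- offset[i] + a                        # transcript coords, 1-based
      lo <- t0 - flank
      hi <- t0 + window - 1L + flank
      core <- substr(tx, max(1L, lo), min(L, hi))
      paste0(strrep("N", max(0L, 1L - lo)), core,
             strrep("N", max(0L, hi - L)))
    }, character(1))
    sc <- predictor(wins)
    if (is.null(dim(sc))) sc <- matrix(sc, ncol = 1,
                                       dimnames = list(NULL, "score"))
    rows[[i]] <- colSums(sc) / rl
  }
  factors <- unique(unlist(lapply(rows, names)))
  if (is.null(factors)) stop("predictor returned no factor columns")
  out <- matrix(NA_real_, length(ts), length(factors),
                dimnames = list(geneIds(ts), factors))
  for (i in seq_len(length(ts)))
    if (!is.null(rows[[i]])) out[i, names(rows[[i]])] <- rows[[i]]
  out
}

#' Read a BED6/narrowPeak file as a peak set
#'
#' Malformed records (start >= end after 0-based half-open conversion) are
#' rejected with a diagnostic.
#'
#' @param path Path to a BED6 or narrowPeak file (0-based half-open).
#' @return A \linkS4class{GRanges}.
#' @export
readPeakBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  bad <- df[[2]] >= df[[3]]
  if (any(bad)) {
    warning(sum(bad), " malformed interval record(s) rejected in ", path)
    df <- df[!bad, , drop = FALSE]
  }
  GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = if (ncol(df) >= 6) df[[6]] else "*")
}

#' Strand-aware peak-count features
#'
#' Counts, for each gene body and each factor's peak set, the peaks
#' overlapping the gene on the same strand by at least 1 bp, then applies
#' log10(count + 1). Genes without peaks get 0.
#'
#' @param genes A named \linkS4class{GRanges} of gene bodies (names are
#'   gene IDs; for peak counting the gene body is the union of the gene's
#'   annotated transcript spans).
#' @param peaks Named list of \linkS4class{GRanges}, one per factor.
#' @param group Feature-group letter for the resulting columns (e.g.
#'   \code{"E"} for CLIP, \code{"e"} for eCLIP, \code{"m"} for m6A-pathway
#'   peaks, \code{"P"} for PAR-CLIP).
#' @return List with \code{values} (gene-by-factor matrix of transformed
#'   counts) and \code{groups}.
#' @export
peakCountFeatures <- function(genes, peaks, group = "E") {
  stopifnot(!is.null(names(genes)), is.list(peaks),
            !is.null(names(peaks)))
  vals <- sapply(peaks, function(p)
    GenomicRanges::countOverlaps(genes, p, minoverlap = 1L,
                                 ignore.strand = FALSE))
  vals <- log10(as.matrix(vals) + 1)
  rownames(vals) <- names(genes)
  list(values = vals, groups = rep(group, ncol(vals)))
}

#' Attach an external per-gene score table as feature columns
#'
#' Ingests external score tables (microRNA repression, RIP-seq,
#' translational efficiency, ...) against a declared gene universe.
#' Cumulative miRNA context scores are conventionally negated so that
#' larger means more repression. Duplicate gene rows are averaged with a
#' warning; unmapped genes become missing (to be imputed or dropped by the
#' regression configuration).
#'
#' @param table A \code{data.frame} whose first column is \code{gene_id}
#'   and remaining columns are numeric scores, or a path to such a TSV.
#' @param gene_universe Character vector of gene IDs defining row order.
#' @param group Feature-group letter for these columns.
#' @param transform \code{"negate"}, \code{"log10p1"}, or
#'   \code{"identity"}.
#' @return List with \code{values} (gene-by-score matrix) and
#'   \code{groups}.
#' @export
ingestScoreTable <- function(table, gene_universe, group,
                             transform = c("identity", "negate",
                                           "log10p1")) {
  transform <- match.arg(transform)
  if (is.character(table))
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  stopifnot(colnames(table)[1] == "gene_id", ncol(table) >= 2)
  if (anyDuplicated(table$gene_id)) {
    warning("duplicate gene rows averaged")
    table <- stats::aggregate(. ~ gene_id, data = table, FUN = mean,
                              na.action = stats::na.pass)
  }
  vals <- as.matrix(table[, -1, drop = FALSE])
  rownames(vals) <- table$gene_id
  vals <- switch(transform, identity = vals, negate = -vals,
                 log10p1 = log10(vals + 1))
  out <- matrix(NA_real_, length(gene_universe), ncol(vals),
                dimnames = list(gene_universe, colnames(vals)))
  hit <- intersect(gene_universe, rownames(vals))
  out[hit, ] <- vals[hit, , drop = FALSE]
  list(values = out, groups = rep(group, ncol(out)))
}

#' Impute missing feature cells from anchor features
#'
#' Fills missing cells of each feature column by a linear predictor fitted
#' on the complete anchor columns (the basic mRNA features), using the
#' column's observed rows. Observed cells are unchanged; all-missing
#' columns are dropped with a warning.
#'
#' @param f A \linkS4class{FeatureTable}.
#' @param anchors Character vector of anchor column names (must be
#'   complete).
#' @return A \linkS4class{FeatureTable}.
#' @export
imputeFeatureMissing <- function(f, anchors) {
  vals <- featureValues(f)
  groups <- featureGroups(f)
  stopifnot(all(anchors %in% colnames(vals)))
  A <- vals[, anchors, drop = FALSE]
  if (anyNA(A)) stop("anchor columns must be complete")
  X <- cbind(1, A)
  drop_cols <- integer()
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss)) { drop_cols <- c(drop_cols, j); next }
    fit <- stats::lm.fit(X[!miss, , drop = FALSE], v[!miss])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    vals[miss, j] <- drop(X[miss, , drop = FALSE] %*% beta)
  }
  if (length(drop_cols)) {
    warning(length(drop_cols), " all-missing feature column(s) dropped: ",
            paste(colnames(vals)[drop_cols], collapse = ", "))
    vals <- vals[, -drop_cols, drop = FALSE]
    groups <- groups[-drop_cols]
  }
  FeatureTable(vals, groups)
}

#' Assemble sequence-derived feature groups into a FeatureTable
#'
#' Computes the requested sequence-derived groups from a
#' \linkS4class{TranscriptSet}: B (basic), C (codons), 5/O/3 (k-mer
#' frequencies of the 5'UTR/ORF/3'UTR). Externally derived groups (M, S, D,
#' E, e, m, P, R) are attached afterwards with
#' \code{\link{ingestScoreTable}} / \code{\link{peakCountFeatures}} via
#' \code{\link{cbindFeatures}}.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param groups Character vector of group letters among B, C, 5, O, 3.
#' @return A \linkS4class{FeatureTable}.
#' @export
buildFeatureTable <- function(ts, groups = c("B", "C")) {
  stopifnot(all(groups %in% c("B", "C", "5", "O", "3")))
  parts <- lapply(groups, function(g) {
    switch(g,
           B = list(values = basicFeatures(ts), groups = rep("B", 8L)),
           C = {
             v <- codonFrequencies(ts)
             list(values = v, groups = rep("C", ncol(v)))
           },
           "5" = {
             v <- kmerFrequencies(ts, "utr5")
             list(values = v, groups = rep("5", ncol(v)))
           },
           O = {
             v <- kmerFrequencies(ts, "orf")
             list(values = v, groups = rep("O", ncol(v)))
           },
           "3" = {
             v <- kmerFrequencies(ts, "utr3")
             list(values = v, groups = rep("3", ncol(v)))
           })
  })
  FeatureTable(do.call(cbind, lapply(parts, `[[`, "values")),
               unlist(lapply(parts, `[[`, "groups")))
}

#' Bind feature columns onto a FeatureTable
#'
#' @param f A \linkS4class{FeatureTable} (or \code{NULL}).
#' @param ... Lists with \code{values}/\code{groups} (as returned by
#'   \code{\link{peakCountFeatures}} and \code{\link{ingestScoreTable}}),
#'   or further \linkS4class{FeatureTable}s; rows are matched by gene ID.
#' @return A \linkS4class{FeatureTable}.
#' @export
cbindFeatures <- function(f, ...) {
  parts <- list(...)
  vals <- if (is.null(f)) NULL else featureValues(f)
  groups <- if (is.null(f)) character() else featureGroups(f)
  for (p in parts) {
    if (is(p, "FeatureTable"))
      p <- list(values = featureValues(p), groups = featureGroups(p))
    v <- p$values
    if (!is.null(vals)) {
      v <- v[match(rownames(vals), rownames(v)), , drop = FALSE]
      rownames(v) <- rownames(vals)
    }
    vals <- if (is.null(vals)) v else cbind(vals, v)
    groups <- c(groups, p$groups)
  }
  FeatureTable(vals, groups)
}
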