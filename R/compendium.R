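## Harmonization of heterogeneous mRNA half-life datasets into consensus
## per-gene half-lives, plus the two bias diagnostics (method-class bias on
## sample PC2; cell-type specificity of cross-study correlations).

#' Log-transform raw half-life measurements
#'
#' Applies the unit-aware log transform to a raw gene-by-sample matrix:
#' \code{log10(x + 0.1)} for samples measured in hours, \code{log10(x + 1)}
#' for samples measured in minutes. Samples deposited as degradation rates
#' are transformed the same way and then negated, so that larger always
#' means longer-lived. Duplicate gene IDs are averaged after the transform.
#'
#' Rate samples whose values are not all positive are assumed to be on a
#' log scale already and are only negated.
#'
#' @param values Raw gene-by-sample matrix (gene rownames, sample colnames,
#'   \code{NA} = missing), or a long \code{data.frame} with columns
#'   \code{gene_id}, \code{sample_id}, \code{value}.
#' @param meta Per-sample metadata (see \code{\link{HalfLifeMatrix}}).
#' @return A \linkS4class{HalfLifeMatrix} at stage \code{"transformed"}.
#' @examples
#' m <- matrix(c(0.9, 2, 4, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), study = "A",
#'                    species = "human", cell_type = "HeLa", method = "4sU",
#'                    unit = "hours", is_degradation_rate = FALSE)
#' hlValues(preprocessHalflives(m, meta))["g1", "s1"]  # log10(0.9+0.1) == 0
#' @export
preprocessHalflives <- function(values, meta) {
  if (is.data.frame(values)) {
    stopifnot(all(c("gene_id", "sample_id", "value") %in% colnames(values)))
    genes <- unique(values$gene_id)
    samples <- unique(values$sample_id)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    ## duplicates resolved later, post-transform; keep all records for now
    values$.row <- match(values$gene_id, genes)
    values$.col <- match(values$sample_id, samples)
  } else {
    m <- values
  }
  meta <- as.data.frame(meta)
  if (!"method_class" %in% colnames(meta))
    meta$method_class <- methodClass(meta$method)
  if (!"is_degradation_rate" %in% colnames(meta))
    meta$is_degradation_rate <- FALSE

  transform_col <- function(v, unit, is_rate, sample_id) {
    if (is_rate) {
      obs <- v[!is.na(v)]
      if (length(obs) && all(obs > 0)) {
        pc <- if (identical(unit, "minutes")) 1 else 0.1
        return(-log10(v + pc))
      }
      return(-v)  # already log-scale rates
    }
    if (is.na(unit) || !unit %in% c("hours", "minutes"))
      stop("unknown unit for sample ", sample_id)
    neg <- which(!is.na(v) & v < 0)
    if (length(neg)) {
      warning(sprintf("sample %s: %d negative half-life value(s) rejected",
                      sample_id, length(neg)))
      v[neg] <- NA_real_
    }
    pc <- if (unit == "hours") 0.1 else 1
    log10(v + pc)
  }

  if (is.data.frame(values)) {
    for (j in seq_along(samples)) {
      sel <- values$.col == j
      mm <- meta[match(samples[j], meta$sample_id), ]
      tv <- transform_col(values$value[sel], mm$unit,
                          isTRUE(mm$is_degradation_rate), samples[j])
      ## duplicate gene IDs replaced by their transformed mean
      agg <- tapply(tv, values$.row[sel], mean, na.rm = TRUE)
      m[as.integer(names(agg)), j] <- as.numeric(agg)
    }
    out <- m
  } else {
    out <- m
    for (j in seq_len(ncol(m))) {
      mm <- meta[match(colnames(m)[j], meta$sample_id), ]
      out[, j] <- transform_col(m[, j], mm$unit,
                                isTRUE(mm$is_degradation_rate),
                                colnames(m)[j])
    }
    if (anyDuplicated(rownames(out))) {
      g <- rownames(out)
      sums <- rowsum(ifelse(is.na(out), 0, out), g)
      cnts <- rowsum((!is.na(out)) + 0, g)
      avg <- sums / cnts
      avg[cnts == 0] <- NA_real_
      out <- avg[unique(g), , drop = FALSE]
    }
  }
  out[is.nan(out)] <- NA_real_
  HalfLifeMatrix(out, meta, stage = "transformed")
}

#' Filter genes by measurement support
#'
#' Retains exactly the genes with at least \code{min_samples} non-missing
#' measurements (the compendium uses 10 for human and 5 for mouse).
#'
#' @param m A \linkS4class{HalfLifeMatrix} at stage \code{"transformed"}.
#' @param min_samples Minimum number of non-missing samples per gene.
#' @return A \linkS4class{HalfLifeMatrix} at stage \code{"filtered"}.
#' @export
filterGenes <- function(m, min_samples) {
  stopifnot(is(m, "HalfLifeMatrix"))
  if (hlStage(m) != "transformed")
    stop("filterGenes expects stage 'transformed', got '", hlStage(m), "'")
  x <- hlValues(m)
  if (min_samples > ncol(x))
    stop("min_samples (", min_samples, ") exceeds sample count (",
         ncol(x), ")")
  keep <- rowSums(!is.na(x)) >= min_samples
  HalfLifeMatrix(x[keep, , drop = FALSE], sampleMeta(m),
                 stage = "filtered")
}

#' Z-score each sample column
#'
#' Standardizes the observed entries of each sample to mean 0 and sd 1
#' (sample sd, n-1 denominator); missing entries are untouched. This puts
#' samples deposited in different units or scales on a common footing.
#'
#' @param m A \linkS4class{HalfLifeMatrix} at stage \code{"filtered"}.
#' @return A \linkS4class{HalfLifeMatrix} at stage \code{"standardized"}.
#' @export
standardizeSamples <- function(m) {
  stopifnot(is(m, "HalfLifeMatrix"))
  if (hlStage(m) != "filtered")
    stop("standardizeSamples expects stage 'filtered', got '",
         hlStage(m), "'")
  x <- hlValues(m)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    obs <- v[!is.na(v)]
    if (length(obs) < 2L)
      stop("sample ", colnames(x)[j], " has fewer than 2 observed values")
    s <- stats::sd(obs)
    if (s == 0)
      stop("sample ", colnames(x)[j], " has zero variance")
    x[, j] <- (v - mean(obs)) / s
  }
  HalfLifeMatrix(x, sampleMeta(m), stage = "standardized")
}

## Rank-ncp EM imputation of a standardized matrix. Missing cells are
## initialized with column means of observed values and repeatedly
## overwritten by a rank-ncp SVD reconstruction of the completed,
## column-centered matrix until the largest change on a missing cell falls
## below tol. Observed cells are never touched.
.pcaImputeFixed <- function(x, ncp, tol = 1e-6, max_iter = 1000L,
                            on_fail = c("error", "return")) {
  on_fail <- match.arg(on_fail)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  colmu <- colMeans(x, na.rm = TRUE)
  xc <- x
  for (j in seq_len(ncol(x))) xc[miss[, j], j] <- colmu[j]
  if (ncp == 0L) return(xc)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    mu <- colMeans(xc)
    cx <- sweep(xc, 2, mu)
    sv <- svd(cx, nu = ncp, nv = ncp)
    rec <- sv$u %*% (diag(sv$d[seq_len(ncp)], ncp) %*% t(sv$v))
    rec <- sweep(rec, 2, mu, "+")
    delta <- max(abs(rec[miss] - xc[miss]))
    xc[miss] <- rec[miss]
    if (delta < tol) return(xc)
  }
  if (on_fail == "return") return(xc)
  stop(sprintf(
    "iterative PCA imputation did not converge in %d iterations (last max |delta| = %.3g)",
    max_iter, delta))
}

#' Impute missing half-lives by iterative PCA
#'
#' EM-style low-rank imputation: missing cells are initialized with column
#' means, then repeatedly overwritten with a rank-\code{ncp} SVD
#' reconstruction of the completed matrix until convergence. The number of
#' components is chosen by cross-validated imputation error over the grid
#' \code{0..ncp_max} (additionally masked observed cells; K-fold, seeded),
#' or by a generalized cross-validation approximation.
#'
#' @param m A \linkS4class{HalfLifeMatrix} at stage \code{"standardized"}.
#' @param ncp_max Largest number of components considered (20 is used for
#'   the human compendium, 10 for mouse).
#' @param ncp Optional fixed number of components (skips selection).
#' @param method \code{"cv"} (K-fold on masked cells) or \code{"gcv"}.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed for the CV cell masking.
#' @param tol Convergence tolerance on the max absolute change of imputed
#'   cells.
#' @param max_iter Iteration cap.
#' @return List with \code{matrix} (a \linkS4class{HalfLifeMatrix} at stage
#'   \code{"imputed"}), \code{ncp} (the chosen rank) and \code{cv_error}
#'   (per-rank imputation MSE, when selection ran).
#' @export
imputeIterativePCA <- function(m, ncp_max, ncp = NULL,
                               method = c("cv", "gcv"), cv_folds = 5L,
                               seed = 1L, tol = 1e-6, max_iter = 1000L) {
  stopifnot(is(m, "HalfLifeMatrix"))
  if (hlStage(m) != "standardized")
    stop("imputeIterativePCA expects stage 'standardized', got '",
         hlStage(m), "'")
  method <- match.arg(method)
  x <- hlValues(m)
  if (ncp_max < 0 || ncp_max >= ncol(x))
    stop("ncp_max must satisfy 0 <= ncp_max < number of samples")
  if (any(rowSums(!is.na(x)) == 0L))
    stop("gene(s) with all values missing")
  if (any(colSums(!is.na(x)) == 0L))
    stop("sample(s) with all values missing")

  cv_err <- NULL
  if (is.null(ncp)) {
    grid <- 0:ncp_max
    obs_idx <- which(!is.na(x))
    if (method == "cv") {
      rng <- .withSeed(seed, sample.int(length(obs_idx)))
      fold_of <- rep_len(seq_len(cv_folds), length(obs_idx))[order(rng)]
      cv_err <- sapply(grid, function(q) {
        errs <- vapply(seq_len(cv_folds), function(f) {
          xm <- x
          hold <- obs_idx[fold_of == f]
          xm[hold] <- NA_real_
          bad_gene <- rowSums(!is.na(xm)) == 0L
          if (any(bad_gene)) {  # keep such genes out of this fold's error
            hold <- hold[(hold - 1L) %% nrow(x) + 1L != which(bad_gene)[1]]
            xm <- x
            xm[hold] <- NA_real_
          }
          ## rank scoring tolerates slow EM convergence at noisy high
          ## ranks: the 300-iteration iterate is an adequate CV score
          imp <- .pcaImputeFixed(xm, q, tol = 1e-4, max_iter = 300L,
                                 on_fail = "return")
          mean((imp[hold] - x[hold])^2)
        }, numeric(1))
        mean(errs)
      })
      ncp <- grid[which.min(cv_err)]
    } else {
      n_obs <- length(obs_idx)
      cv_err <- sapply(grid, function(q) {
        imp <- .pcaImputeFixed(x, q, tol = 1e-4, max_iter = 300L,
                               on_fail = "return")
        mu <- colMeans(imp)
        cx <- sweep(imp, 2, mu)
        if (q > 0) {
          sv <- svd(cx, nu = q, nv = q)
          fit <- sv$u %*% (diag(sv$d[seq_len(q)], q) %*% t(sv$v))
        } else fit <- 0 * cx
        rss <- sum((cx[obs_idx] - fit[obs_idx])^2)
        df <- q * (nrow(x) + ncol(x) - q)
        (rss / n_obs) / (1 - min(df / n_obs, 0.99))^2
      })
      ncp <- grid[which.min(cv_err)]
    }
    names(cv_err) <- grid
  }
  imp <- .pcaImputeFixed(x, ncp, tol = tol, max_iter = max_iter)
  list(matrix = HalfLifeMatrix(imp, sampleMeta(m), stage = "imputed"),
       ncp = ncp, cv_error = cv_err)
}

#' Quantile-normalize the imputed matrix
#'
#' Forces every sample column onto the identical distribution: the
#' across-sample mean of order statistics. Ties within a column receive the
#' average of the tied quantiles; alternate tie rules would change only the
#' tied entries.
#'
#' @param m A \linkS4class{HalfLifeMatrix} at stage \code{"imputed"}.
#' @return A \linkS4class{HalfLifeMatrix} at stage \code{"normalized"}.
#' @export
quantileNormalize <- function(m) {
  stopifnot(is(m, "HalfLifeMatrix"))
  if (hlStage(m) != "imputed")
    stop("quantileNormalize expects stage 'imputed', got '", hlStage(m), "'")
  x <- hlValues(m)
  if (anyNA(x)) stop("missing values present; impute first")
  qn <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(qn) <- dimnames(x)
  HalfLifeMatrix(qn, sampleMeta(m), stage = "normalized")
}

#' Consensus per-gene half-life as PC1
#'
#' PCA over the processed gene-by-sample matrix (samples as variables,
#' column-centered, unscaled). The first principal component scores are the
#' consensus, cell-type-agnostic half-life phenotype; the sign is anchored
#' so that the scores correlate positively with per-gene means.
#'
#' @param m A \linkS4class{HalfLifeMatrix} at stage \code{"normalized"}.
#' @return A \linkS4class{ConsensusHalfLife}.
#' @export
consensusPC1 <- function(m) {
  stopifnot(is(m, "HalfLifeMatrix"))
  if (hlStage(m) != "normalized")
    stop("consensusPC1 expects stage 'normalized', got '", hlStage(m), "'")
  x <- hlValues(m)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  anchor <- "corr(PC1, per-gene mean) > 0"
  if (stats::cor(scores, rowMeans(x)) < 0) scores <- -scores
  names(scores) <- rownames(x)
  new("ConsensusHalfLife", geneScores = scores,
      varianceExplained = pc$sdev^2 / sum(pc$sdev^2),
      signAnchor = anchor)
}

#' Sample-space PCA for relatedness plots
#'
#' PCA with genes as variables (on the transpose of the processed
#' gene-by-sample matrix): each sample gets coordinates on the first two
#' PCs, used to visualize study relatedness and method-class separation.
#'
#' @param m A \linkS4class{HalfLifeMatrix} at stage \code{"normalized"} (the
#'   \code{"imputed"} stage is also accepted).
#' @return List with \code{coords} (data.frame: sample_id, PC1, PC2, plus
#'   the sample metadata) and \code{variance_explained}.
#' @export
samplePCA <- function(m) {
  stopifnot(is(m, "HalfLifeMatrix"))
  if (!hlStage(m) %in% c("imputed", "normalized"))
    stop("samplePCA expects an imputed or normalized matrix")
  x <- hlValues(m)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  coords <- data.frame(sample_id = colnames(x),
                       PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                       sampleMeta(m), row.names = NULL)
  list(coords = coords,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

## Exact two-sided / one-sided rank-sum p by enumeration over all
## assignments of the pooled midranks (handles ties exactly); falls back to
## the normal approximation when the assignment count is large.
.rankSumTest <- function(x, y, alternative = c("two.sided", "greater"),
                         max_enum = 200000) {
  alternative <- match.arg(alternative)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (choose(n + m, n) <= max_enum) {
    combs <- utils::combn(n + m, n)
    Us <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    p <- if (alternative == "two.sided") {
      mean(abs(Us - n * m / 2) >= abs(U - n * m / 2) - 1e-12)
    } else {
      mean(Us >= U - 1e-12)
    }
    method <- "exact enumeration"
  } else {
    wt <- stats::wilcox.test(x, y, alternative = alternative,
                             exact = FALSE, correct = TRUE)
    p <- wt$p.value
    method <- "normal approximation"
  }
  list(statistic = U, p.value = p, method = method)
}

#' Test for method-class bias on sample PC2
#'
#' Averages PC2 within (study, method class) so replicate-heavy studies
#' count once, then compares pulse-labeling against transcriptional-shutoff
#' study values with a two-sided rank-sum test (exact when feasible,
#' including under ties).
#'
#' @param coords Sample coordinates from \code{\link{samplePCA}} (the
#'   \code{coords} data.frame, or any data.frame with the tested PC
#'   column, \code{study} and \code{method_class}).
#' @param pc Which component to test (default \code{"PC2"}, the axis on
#'   which the method classes separate in the real compendium, where PC1
#'   is dominated by an outlier study; in data without such an outlier
#'   the class axis can be the leading one).
#' @return List with the per-class study-level values, the U statistic, the
#'   p-value and the method used.
#' @export
methodBiasTest <- function(coords, pc = "PC2") {
  stopifnot(all(c(pc, "study", "method_class") %in% colnames(coords)))
  agg <- stats::aggregate(coords[[pc]],
                          by = coords[c("study", "method_class")],
                          FUN = mean)
  split_vals <- split(agg$x, agg$method_class)
  if (!all(c("pulse_labeling", "transcriptional_shutoff") %in%
           names(split_vals)))
    stop("both method classes must be present")
  if (any(vapply(split_vals, length, integer(1)) < 2L))
    stop("need >= 2 study-level values per method class")
  ts <- .rankSumTest(split_vals$pulse_labeling,
                     split_vals$transcriptional_shutoff, "two.sided")
  list(groups = split_vals, statistic = ts$statistic,
       p.value = ts$p.value, method = ts$method)
}

#' Test for cell-type specificity of cross-study correlations
#'
#' Computes the Pearson correlation of every cross-study sample pair
#' (same-study pairs are excluded to avoid replicate inflation), partitions
#' the pairs into same-cell-type and different-cell-type sets, and asks with
#' a one-sided rank-sum test whether same-cell-type correlations exceed
#' different-cell-type ones. With \code{genes = "common"} the correlations
#' use pairwise-complete observations (the pre-imputation measurement
#' support); with \code{"all"} every gene enters (sensible for imputed or
#' normalized matrices).
#'
#' @param m A \linkS4class{HalfLifeMatrix} (any stage at or after
#'   \code{"filtered"}).
#' @param genes \code{"all"} or \code{"common"}.
#' @return List with the pair table, per-partition correlation vectors, the
#'   U statistic and p-value.
#' @export
celltypeSpecificityTest <- function(m, genes = c("all", "common")) {
  stopifnot(is(m, "HalfLifeMatrix"))
  genes <- match.arg(genes)
  x <- hlValues(m)
  meta <- sampleMeta(m)
  ns <- ncol(x)
  pairs <- which(upper.tri(matrix(TRUE, ns, ns)), arr.ind = TRUE)
  keep <- meta$study[pairs[, 1]] != meta$study[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no cross-study sample pairs")
  cors <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (genes == "common")
      stats::cor(x[, i], x[, j], use = "pairwise.complete.obs")
    else stats::cor(x[, i], x[, j])
  }, numeric(1))
  same <- meta$cell_type[pairs[, 1]] == meta$cell_type[pairs[, 2]]
  if (!any(same) || all(same))
    stop("need both same-cell-type and different-cell-type pairs")
  ts <- .rankSumTest(cors[same], cors[!same], "greater")
  list(pairs = data.frame(sample1 = colnames(x)[pairs[, 1]],
                          sample2 = colnames(x)[pairs[, 2]],
                          correlation = cors, same_cell_type = same),
       same = cors[same], different = cors[!same],
       statistic = ts$statistic, p.value = ts$p.value, method = ts$method)
}

#' Run the full harmonization pipeline
#'
#' Convenience wrapper: transform, filter, standardize, impute, quantile
#' normalize, and extract the PC1 consensus plus the sample-space PCA.
#'
#' @param values Raw matrix or long data.frame (see
#'   \code{\link{preprocessHalflives}}).
#' @param meta Per-sample metadata.
#' @param min_samples Gene filter threshold (10 human / 5 mouse).
#' @param ncp_max Largest imputation rank considered.
#' @param exclude_study Character vector of study IDs dropped before
#'   processing (outlier studies).
#' @param ncp Optional fixed imputation rank.
#' @param seed Seed for the imputation-rank cross-validation.
#' @return List with the stage-tagged matrices, \code{consensus}
#'   (\linkS4class{ConsensusHalfLife}), \code{sample_pca} and \code{ncp}.
#' @export
runConsensusPipeline <- function(values, meta, min_samples, ncp_max,
                                 exclude_study = character(), ncp = NULL,
                                 seed = 1L) {
  meta <- as.data.frame(meta)
  if (length(exclude_study)) {
    keep <- !meta$study %in% exclude_study
    meta <- meta[keep, , drop = FALSE]
    if (is.data.frame(values)) {
      values <- values[values$sample_id %in% meta$sample_id, , drop = FALSE]
    } else {
      values <- values[, colnames(values) %in% meta$sample_id, drop = FALSE]
    }
  }
  transformed <- preprocessHalflives(values, meta)
  filtered <- filterGenes(transformed, min_samples)
  standardized <- standardizeSamples(filtered)
  imp <- imputeIterativePCA(standardized, ncp_max = ncp_max, ncp = ncp,
                            seed = seed)
  normalized <- quantileNormalize(imp$matrix)
  list(transformed = transformed, filtered = filtered,
       standardized = standardized, imputed = imp$matrix,
       normalized = normalized, ncp = imp$ncp,
       consensus = consensusPC1(normalized),
       sample_pca = samplePCA(normalized))
}
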