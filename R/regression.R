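## L1-regularized linear modeling of half-life from feature groups, nested
## model comparison over fixed folds, and coefficient interpretation.

#' Resolve a model code into feature columns
#'
#' A model code is a string over the feature-group alphabet (e.g.
#' \code{"BC3MS"}): each letter selects one group of a
#' \linkS4class{FeatureTable}. Duplicate letters are rejected.
#'
#' @param f A \linkS4class{FeatureTable}.
#' @param code Model code string.
#' @return Integer vector of selected column indices (with the code as an
#'   attribute).
#' @export
resolveModelSpec <- function(f, code) {
  letters_ <- strsplit(code, "")[[1]]
  if (anyDuplicated(letters_)) stop("duplicate letters in model code ", code)
  if (!all(letters_ %in% .GROUP_ALPHABET))
    stop("unknown group letter(s) in ", code)
  groups <- featureGroups(f)
  missing_grp <- setdiff(letters_, unique(groups))
  if (length(missing_grp))
    stop("feature table lacks group(s): ",
         paste(missing_grp, collapse = ", "))
  idx <- which(groups %in% letters_)
  attr(idx, "code") <- code
  idx
}

## Assign genes to inner CV folds deterministically from a seed.
.innerFoldId <- function(n, nfolds, seed)
  .withSeed(seed, sample(rep_len(seq_len(nfolds), n)))

#' Lasso coefficients at a fixed penalty
#'
#' Thin wrapper over the L1 solver used throughout the module; exposed so
#' that closed-form checks can target the exact fitting path.
#'
#' @param X Numeric design matrix.
#' @param y Numeric response.
#' @param lambda Penalty value (on the 1/(2n) RSS scale of glmnet).
#' @param intercept Fit an intercept?
#' @return Named numeric coefficient vector (excluding the intercept).
#' @export
lassoCoefficients <- function(X, y, lambda, intercept = TRUE) {
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, intercept = intercept)
  b <- as.numeric(fit$beta[, 1])
  names(b) <- rownames(fit$beta)
  b
}

#' Cross-validated lasso with fixed outer folds
#'
#' Features and target are z-scored (globally by default, reproducing the
#' published preprocessing; fold-wise standardization is available but
#' leaks no test information and will generally differ slightly). For each
#' outer fold, the penalty is chosen by inner 10-fold CV on the training
#' portion over a 100-value log-spaced grid spanning four orders of
#' magnitude below the smallest empty-support penalty, the model is refit
#' at the chosen penalty, and predictions are emitted for the held-out
#' fold.
#'
#' @param f A \linkS4class{FeatureTable} (no missing values).
#' @param target A \linkS4class{ConsensusHalfLife} or named numeric vector.
#' @param folds Named integer vector: gene -> outer fold index.
#' @param code Optional model code restricting the feature groups.
#' @param standardize \code{"global"} or \code{"fold"} (fold-wise scaling
#'   estimated on training data only).
#' @param lambda_rule \code{"min"} (minimum mean inner-CV MSE) or
#'   \code{"1se"}.
#' @param seed Seed for the inner fold assignment.
#' @return List with \code{predictions} (named, concatenated over held-out
#'   folds), \code{fold_r} (per-fold held-out Pearson r; 0 with a flag for
#'   degenerate constant predictions), \code{lambda} (per fold),
#'   \code{degenerate} (logical per fold), \code{code}.
#' @export
fitLassoCV <- function(f, target, folds, code = NULL,
                       standardize = c("global", "fold"),
                       lambda_rule = c("min", "1se"), seed = 1L) {
  standardize <- match.arg(standardize)
  lambda_rule <- match.arg(lambda_rule)
  y_all <- if (is(target, "ConsensusHalfLife")) geneScores(target)
           else target
  vals <- featureValues(f)
  genes <- Reduce(intersect, list(rownames(vals), names(y_all),
                                  names(folds)))
  if (!length(genes)) stop("no genes shared by features, target and folds")
  X <- vals[genes, , drop = FALSE]
  if (!is.null(code)) X <- X[, resolveModelSpec(f, code), drop = FALSE]
  if (anyNA(X)) stop("missing feature values; impute or drop first")
  y <- y_all[genes]
  if (stats::sd(y) == 0) stop("constant target")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped")
    X <- X[, !const, drop = FALSE]
  }
  fold_of <- folds[genes]
  fold_ids <- sort(unique(fold_of))
  if (standardize == "global") {
    X <- scale(X)
    y <- as.numeric(scale(y))
    names(y) <- genes
  }
  preds <- stats::setNames(rep(NA_real_, length(genes)), genes)
  fold_r <- lambda_used <- stats::setNames(numeric(length(fold_ids)),
                                           fold_ids)
  degenerate <- stats::setNames(logical(length(fold_ids)), fold_ids)
  inner_seeds <- .childSeeds(seed, length(fold_ids))
  for (k in seq_along(fold_ids)) {
    te <- fold_of == fold_ids[k]
    Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
    Xte <- X[te, , drop = FALSE]
    if (standardize == "fold") {
      mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
      ym <- mean(ytr); ys <- stats::sd(ytr)
      ytr <- (ytr - ym) / ys
    }
    foldid <- .innerFoldId(nrow(Xtr), 10L, inner_seeds[k])
    cvfit <- glmnet::cv.glmnet(Xtr, ytr, alpha = 1, foldid = foldid,
                               nlambda = 100, lambda.min.ratio = 1e-4,
                               standardize = FALSE)
    lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    p <- drop(stats::predict(cvfit, newx = Xte, s = lam))
    if (standardize == "fold") p <- p * ys + ym
    preds[te] <- p
    lambda_used[k] <- lam
    if (stats::sd(p) == 0 || stats::sd(y[te]) == 0) {
      fold_r[k] <- 0
      degenerate[k] <- TRUE
    } else fold_r[k] <- stats::cor(p, y[te])
  }
  list(predictions = preds, fold_r = fold_r, lambda = lambda_used,
       degenerate = degenerate, code = if (is.null(code)) "all" else code)
}

## One-sided paired t-test p-value for H1: mean(d) > 0, with the
## degenerate-variance conventions: all-zero differences carry no evidence
## (p = 1); constant nonzero differences are treated as infinitely
## concordant (p = 0 or 1 by sign).
.pairedOneSidedP <- function(d) {
  if (stats::sd(d) == 0) {
    if (mean(d) > 0) return(0)
    return(1)
  }
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  stats::pt(tstat, df = n - 1, lower.tail = FALSE)
}

#' Nested feature-group model comparison
#'
#' Fits each model code with \code{\link{fitLassoCV}} on identical outer
#' folds and, for each declared (simpler, complex) pair, performs a
#' one-sided paired t-test on the per-fold held-out correlations (H1:
#' complex > simpler), Bonferroni-adjusted over the declared number of
#' comparisons. A group is marked contributing when its adjusted p falls
#' below \code{alpha}.
#'
#' @param f A \linkS4class{FeatureTable}.
#' @param target Consensus half-life (see \code{\link{fitLassoCV}}).
#' @param folds Named outer fold assignment.
#' @param codes Character vector of model codes, simple to complex.
#' @param comparisons List of \code{c(simpler, complex)} pairs; default is
#'   consecutive codes.
#' @param alpha Significance level on adjusted p-values (0.05).
#' @param ... Passed to \code{\link{fitLassoCV}}.
#' @return List with \code{fold_r} (matrix: folds x models),
#'   \code{comparisons} (data.frame with raw and Bonferroni-adjusted
#'   p-values and winners), and \code{fits}.
#' @export
compareNestedModels <- function(f, target, folds, codes,
                                comparisons = NULL, alpha = 0.05, ...) {
  fits <- lapply(codes, function(cd)
    fitLassoCV(f, target, folds, code = cd, ...))
  names(fits) <- codes
  rmat <- sapply(fits, `[[`, "fold_r")
  if (is.null(comparisons))
    comparisons <- lapply(seq_len(length(codes) - 1L), function(i)
      c(codes[i], codes[i + 1L]))
  n_tests <- length(comparisons)
  tab <- do.call(rbind, lapply(comparisons, function(cp) {
    d <- rmat[, cp[2]] - rmat[, cp[1]]
    p <- .pairedOneSidedP(d)
    data.frame(simpler = cp[1], complex = cp[2],
               mean_delta_r = mean(d), p = p,
               p_adjusted = min(1, p * n_tests))
  }))
  tab$contributing <- tab$p_adjusted < alpha
  tab$winner <- ifelse(tab$contributing, tab$complex, tab$simpler)
  list(fold_r = rmat, comparisons = tab, fits = fits)
}

#' Interpret a lasso model: top coefficients and collinearity sets
#'
#' Refits the model on the full dataset at a penalty chosen by 10-fold CV,
#' ranks coefficients by magnitude, and reports, for each of the top
#' features, all other features sharing an absolute Pearson correlation at
#' or above the threshold (lasso picks one member of a correlated set
#' essentially arbitrarily; the sets are the honest unit of
#' interpretation).
#'
#' @param f A \linkS4class{FeatureTable}.
#' @param target Consensus half-life or named numeric vector.
#' @param code Model code.
#' @param top_n Number of top-magnitude coefficients to report (30).
#' @param corr_threshold Absolute-correlation threshold (0.8).
#' @param seed Seed for the CV fold assignment.
#' @return List with \code{coefficients} (data.frame: feature, group,
#'   coefficient, ordered by |coefficient|), \code{lambda}, and
#'   \code{collinear} (named list: top feature -> data.frame of correlated
#'   features and their correlations).
#' @export
interpretModel <- function(f, target, code, top_n = 30L,
                           corr_threshold = 0.8, seed = 1L) {
  y_all <- if (is(target, "ConsensusHalfLife")) geneScores(target)
           else target
  vals <- featureValues(f)
  genes <- intersect(rownames(vals), names(y_all))
  X <- vals[genes, resolveModelSpec(f, code), drop = FALSE]
  groups <- featureGroups(f)[resolveModelSpec(f, code)]
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]; groups <- groups[keep]
  Xs <- scale(X)
  ys <- as.numeric(scale(y_all[genes]))
  foldid <- .innerFoldId(nrow(Xs), 10L, seed)
  cvfit <- glmnet::cv.glmnet(Xs, ys, alpha = 1, foldid = foldid,
                             nlambda = 100, lambda.min.ratio = 1e-4,
                             standardize = FALSE)
  beta <- lassoCoefficients(Xs, ys, cvfit$lambda.min)
  support <- beta[beta != 0]
  ord <- order(abs(support), decreasing = TRUE)
  top <- support[ord][seq_len(min(top_n, length(support)))]
  collinear <- lapply(names(top), function(feat) {
    r <- drop(stats::cor(Xs[, feat], Xs))
    hits <- which(abs(r) >= corr_threshold & colnames(Xs) != feat)
    df <- data.frame(feature = colnames(Xs)[hits], correlation = r[hits])
    df[order(-abs(df$correlation)), , drop = FALSE]
  })
  names(collinear) <- names(top)
  list(coefficients = data.frame(
         feature = names(top),
         group = groups[match(names(top), colnames(X))],
         coefficient = as.numeric(top)),
       lambda = cvfit$lambda.min, collinear = collinear)
}
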