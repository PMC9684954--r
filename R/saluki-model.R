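## The hybrid convolutional/recurrent half-life regressor: construction,
## parameter accounting, forward/backward orchestration, joint two-species
## training, and ensembling.

#' Hyperparameters of the half-life regressor
#'
#' Defaults are the published full-scale configuration: 12,288-nt inputs,
#' 64 channels, width-5 convolutions, width-2 pooling through 7 pooling
#' steps (an initial convolution plus 6 further blocks) down to 128-nt
#' resolution, a backward GRU, dropout 0.3, L2 1e-3 on weights, Adam with
#' learning rate 1e-3, beta1 0.9, beta2 0.98, global-norm gradient
#' clipping at 0.5, batches of 64, and early-stopping patience of 25
#' epochs.
#'
#' @param L_max Input tensor width; must be divisible by
#'   \code{pool^n_blocks}.
#' @param channels Convolution channels (also the GRU and dense width).
#' @param kernel Convolution kernel width.
#' @param pool Pooling width.
#' @param n_blocks Total number of convolution+pooling layers.
#' @param dropout Dropout probability.
#' @param l2 L2 coefficient on convolution, GRU and dense weights.
#' @param lr,beta1,beta2 Adam settings.
#' @param clip_norm Global gradient-norm clip.
#' @param batch Batch size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param augment_shift Stochastic training augmentation: each
#'   presentation of a sequence is shifted by a uniform offset in
#'   \code{-augment_shift..augment_shift} nt (zero-filled), discouraging
#'   absolute-position memorization. 0 disables.
#' @param heads Species heads.
#' @return Named list of hyperparameters.
#' @export
salukiHyperparams <- function(L_max = 12288L, channels = 64L, kernel = 5L,
                              pool = 2L, n_blocks = 7L, dropout = 0.3,
                              l2 = 0.001, lr = 0.001, beta1 = 0.9,
                              beta2 = 0.98, clip_norm = 0.5, batch = 64L,
                              patience = 25L, augment_shift = 3L,
                              heads = c("human", "mouse")) {
  h <- list(L_max = as.integer(L_max), channels = as.integer(channels),
            kernel = as.integer(kernel), pool = as.integer(pool),
            n_blocks = as.integer(n_blocks), dropout = dropout, l2 = l2,
            lr = lr, beta1 = beta1, beta2 = beta2, clip_norm = clip_norm,
            batch = as.integer(batch), patience = as.integer(patience),
            augment_shift = as.integer(augment_shift), heads = heads)
  if (h$L_max %% h$pool^h$n_blocks != 0L)
    stop("L_max must be divisible by pool^n_blocks")
  h
}

.l2Names <- function(params)
  grep("(^conv.*_W$)|(^gru_W)|(^dense1_W$)|(^head_.*_W$)", names(params),
       value = TRUE)

#' Build (initialize) a half-life regressor
#'
#' Constructs the parameter set of the network: an initial
#' convolution+dropout+maxpool on the 6-track input, \code{n_blocks - 1}
#' blocks of layer norm, ReLU, convolution, dropout and maxpool, a final
#' layer norm and ReLU, a GRU running backward from the padded 3' end, a
#' shared dense block (batch norm, ReLU, bias-free dense), and one output
#' head (batch norm, ReLU, dense to 1) per species. Layer normalization is
#' used inside the tower because 3' zero padding would corrupt batch
#' statistics.
#'
#' @param hyper Hyperparameters from \code{\link{salukiHyperparams}}.
#' @param seed Integer seed for weight initialization.
#' @return A \linkS4class{SalukiModel}.
#' @examples
#' m <- buildSaluki(salukiHyperparams())
#' salukiParamCount(m)  # 155521
#' @export
buildSaluki <- function(hyper = salukiHyperparams(), seed = 1L) {
  C <- hyper$channels; k <- hyper$kernel
  .withSeed(seed, {
    he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc,
                                                    sd = sqrt(2 / fan)),
                                       nr, nc)
    ortho <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    params <- list(conv1_W = he(k * 6L, C, k * 6L), conv1_b = numeric(C))
    for (b in 2:hyper$n_blocks) {
      params[[paste0("ln", b, "_g")]] <- rep(1, C)
      params[[paste0("ln", b, "_b")]] <- numeric(C)
      params[[paste0("conv", b, "_W")]] <- he(k * C, C, k * C)
      params[[paste0("conv", b, "_b")]] <- numeric(C)
    }
    params$lnr_g <- rep(1, C); params$lnr_b <- numeric(C)
    lim <- sqrt(6 / (C + C))
    params$gru_Wx <- matrix(stats::runif(C * 3L * C, -lim, lim), C, 3L * C)
    params$gru_Wh <- cbind(ortho(C), ortho(C), ortho(C))
    params$gru_bx <- numeric(3L * C)
    params$gru_bh <- numeric(3L * C)
    params$bn1_g <- rep(1, C); params$bn1_b <- numeric(C)
    params$dense1_W <- he(C, C, C)
    for (sp in hyper$heads) {
      params[[paste0("bn2_", sp, "_g")]] <- rep(1, C)
      params[[paste0("bn2_", sp, "_b")]] <- numeric(C)
      params[[paste0("head_", sp, "_W")]] <- he(C, 1L, C)
      params[[paste0("head_", sp, "_b")]] <- 0
    }
    bnStats <- list(bn1 = list(mean = numeric(C), var = rep(1, C)))
    for (sp in hyper$heads)
      bnStats[[paste0("bn2_", sp)]] <- list(mean = numeric(C),
                                            var = rep(1, C))
    new("SalukiModel", params = params, hyper = hyper, bnStats = bnStats,
        log = list())
  })
}

#' Count trainable parameters
#'
#' The reported count follows the per-species convention (shared trunk
#' plus one output head): the parameters active in a single forward pass.
#' \code{heads = "all"} counts every head.
#'
#' @param x A \linkS4class{SalukiModel} (or hyperparameter list, which is
#'   instantiated first).
#' @param heads \code{"per_species"} or \code{"all"}.
#' @return Integer parameter count.
#' @export
salukiParamCount <- function(x, heads = c("per_species", "all")) {
  heads <- match.arg(heads)
  if (!is(x, "SalukiModel")) x <- buildSaluki(x)
  params <- x@params
  if (heads == "per_species") {
    sps <- x@hyper$heads
    drop_sp <- sps[-1]
    if (length(drop_sp)) {
      pat <- paste0("_(", paste(drop_sp, collapse = "|"), ")_")
      params <- params[!grepl(pat, names(params))]
    }
  }
  sum(vapply(params, length, integer(1)))
}

## ---- forward / backward ----------------------------------------------------

## Xb: 6 x (B * L_max) channels-by-positions batch. Returns predictions
## and (when training) the caches required for the backward pass. Dropout
## consumes the current RNG stream.
.salukiForward <- function(params, hyper, Xb, B, species, training = FALSE,
                           bnStats = NULL) {
  C <- hyper$channels; k <- hyper$kernel
  L <- hyper$L_max
  keep <- 1 - hyper$dropout
  caches <- list(blocks = vector("list", hyper$n_blocks), B = B,
                 species = species)
  X <- Xb
  for (b in seq_len(hyper$n_blocks)) {
    blk <- list(L = L)
    if (b > 1L) {
      ln <- .cppLnReluForward(X, params[[paste0("ln", b, "_g")]],
                              params[[paste0("ln", b, "_b")]], .LN_EPS)
      blk$ln <- ln
      A <- ln$out
    } else {
      A <- X
      blk$Xin <- X
    }
    Z <- .cppConvForward(A, params[[paste0("conv", b, "_W")]],
                         params[[paste0("conv", b, "_b")]], B, L, k)
    if (training && hyper$dropout > 0) {
      dp <- .cppDropoutForward(Z, keep)
      blk$drop_mask <- dp$mask
      Z <- dp$out
    }
    pool <- .cppPoolForward(Z, B, L)
    blk$pool_mask <- pool$mask
    X <- pool$out
    caches$blocks[[b]] <- blk
    L <- L %/% hyper$pool
  }
  T_ <- L
  lnr <- .cppLnReluForward(X, params$lnr_g, params$lnr_b, .LN_EPS)
  caches$lnr <- lnr
  R <- lnr$out
  gru <- .gruForward(R, params$gru_Wx, params$gru_Wh, params$gru_bx,
                     params$gru_bh, B, T_)
  caches$gru <- gru; caches$T <- T_
  H <- gru$out
  bn1 <- .bnForward(H, params$bn1_g, params$bn1_b, bnStats$bn1, training)
  if (training) bnStats$bn1 <- bn1$stats
  caches$bn1 <- bn1[c("xhat", "inv")]
  caches$H <- H
  caches$relu1 <- bn1$out > 0
  D1in <- bn1$out * caches$relu1
  caches$D1in <- D1in
  D1 <- D1in %*% params$dense1_W
  bn2key <- paste0("bn2_", species)
  bn2 <- .bnForward(D1, params[[paste0(bn2key, "_g")]],
                    params[[paste0(bn2key, "_b")]],
                    bnStats[[bn2key]], training)
  if (training) bnStats[[bn2key]] <- bn2$stats
  caches$bn2 <- bn2[c("xhat", "inv")]
  caches$D1 <- D1
  caches$relu2 <- bn2$out > 0
  Hd <- bn2$out * caches$relu2
  caches$Hd <- Hd
  pred <- drop(Hd %*% params[[paste0("head_", species, "_W")]]) +
    params[[paste0("head_", species, "_b")]]
  list(pred = pred, caches = if (training) caches else NULL,
       bnStats = bnStats)
}

.salukiBackward <- function(params, hyper, caches, dpred) {
  B <- caches$B; k <- hyper$kernel
  sp <- caches$species
  g <- list()
  dpred <- matrix(dpred, ncol = 1)
  g[[paste0("head_", sp, "_W")]] <- crossprod(caches$Hd, dpred)
  g[[paste0("head_", sp, "_b")]] <- sum(dpred)
  dHd <- tcrossprod(dpred, params[[paste0("head_", sp, "_W")]])
  dbn2out <- dHd * caches$relu2
  bn2key <- paste0("bn2_", sp)
  bb <- .bnBackward(dbn2out, caches$bn2, params[[paste0(bn2key, "_g")]])
  g[[paste0(bn2key, "_g")]] <- bb$dgamma
  g[[paste0(bn2key, "_b")]] <- bb$dbeta
  dD1 <- bb$dX
  g$dense1_W <- crossprod(caches$D1in, dD1)
  dD1in <- tcrossprod(dD1, params$dense1_W)
  dbn1out <- dD1in * caches$relu1
  b1 <- .bnBackward(dbn1out, caches$bn1, params$bn1_g)
  g$bn1_g <- b1$dgamma; g$bn1_b <- b1$dbeta
  dH <- b1$dX
  gb <- .gruBackward(dH, caches$gru, params$gru_Wx, params$gru_Wh, B,
                     caches$T)
  g$gru_Wx <- gb$dWx; g$gru_Wh <- gb$dWh
  g$gru_bx <- gb$dbx; g$gru_bh <- gb$dbh
  lb <- .cppLnReluBackward(gb$dX, caches$lnr$out, caches$lnr$xhat,
                           caches$lnr$inv, params$lnr_g)
  g$lnr_g <- lb$dgamma; g$lnr_b <- lb$dbeta
  dX <- lb$dX
  keep <- 1 - hyper$dropout
  for (b in rev(seq_len(hyper$n_blocks))) {
    blk <- caches$blocks[[b]]
    dZ <- .cppPoolBackward(dX, blk$pool_mask, B, blk$L)
    if (!is.null(blk$drop_mask))
      dZ <- .cppDropoutBackward(dZ, blk$drop_mask, keep)
    A <- if (b > 1L) blk$ln$out else blk$Xin
    cb <- .cppConvBackward(dZ, A, params[[paste0("conv", b, "_W")]], B,
                           blk$L, k, need_dx = b > 1L)
    g[[paste0("conv", b, "_W")]] <- cb$dW
    g[[paste0("conv", b, "_b")]] <- cb$db
    if (b > 1L) {
      lb2 <- .cppLnReluBackward(cb$dX, blk$ln$out, blk$ln$xhat,
                                blk$ln$inv, params[[paste0("ln", b, "_g")]])
      g[[paste0("ln", b, "_g")]] <- lb2$dgamma
      g[[paste0("ln", b, "_b")]] <- lb2$dbeta
      dX <- lb2$dX
    } else dX <- cb$dX
  }
  g
}

## Batch assembly in the channels x positions layout of the layer
## primitives: each L x 6 tensor contributes L columns.
.stackTensors <- function(tensors, idx)
  do.call(cbind, lapply(tensors[idx], t))

## 3'-ward (s > 0) or 5'-ward (s < 0) shift of an L x 6 tensor with zero
## fill; used by the stochastic training augmentation.
.shiftTensor <- function(t, s) {
  if (s == 0L) return(t)
  L <- nrow(t)
  out <- matrix(0, L, ncol(t))
  if (s > 0L) out[(1L + s):L, ] <- t[1:(L - s), ]
  else out[1:(L + s), ] <- t[(1L - s):L, ]
  out
}

## Inference over a tensor list in batches; returns numeric predictions.
.predictTensors <- function(model, tensors, species, batch = NULL) {
  hyper <- model@hyper
  if (is.null(batch)) batch <- hyper$batch
  n <- length(tensors)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    Xb <- .stackTensors(tensors, i:j)
    fw <- .salukiForward(model@params, hyper, Xb, j - i + 1L, species,
                         training = FALSE, bnStats = model@bnStats)
    out[i:j] <- fw$pred
    i <- j + 1L
  }
  out
}

#' Predict half-life (z-score units) for encoded mRNAs
#'
#' @param model A trained \linkS4class{SalukiModel}.
#' @param encoded An \linkS4class{EncodedRNASet}, or a list of
#'   \code{L_max x 6} tensors.
#' @param species Head to use; defaults to the per-mRNA species tags of
#'   \code{encoded}.
#' @param batch Inference batch size.
#' @return Named numeric predictions (z-score units of the training
#'   target).
#' @export
predictSaluki <- function(model, encoded, species = NULL, batch = NULL) {
  if (is(encoded, "EncodedRNASet")) {
    stopifnot(encoded@Lmax == model@hyper$L_max)
    tensors <- encoded@tensors
    ids <- encoded@geneId
    sp_tags <- encoded@species
  } else {
    tensors <- encoded
    ids <- names(encoded)
    sp_tags <- NULL
  }
  if (is.null(species)) {
    if (is.null(sp_tags)) stop("species required for raw tensor input")
    out <- numeric(length(tensors))
    for (sp in unique(sp_tags)) {
      sel <- sp_tags == sp
      out[sel] <- .predictTensors(model, tensors[sel], sp, batch)
    }
  } else {
    out <- .predictTensors(model, tensors, species, batch)
  }
  names(out) <- ids
  out
}

## ---- training --------------------------------------------------------------

#' Train one half-life regressor
#'
#' Joint two-species training on strictly alternating per-species batches
#' (shared trunk, species-specific heads; the epoch ends when the larger
#' species is exhausted, the smaller is recycled), MSE loss, Adam with
#' global-norm gradient clipping, targets z-scored within species. After
#' every epoch the validation Pearson correlation is computed (averaged
#' over species); training stops after \code{patience} epochs without
#' improvement or at \code{max_epochs}, and the parameters with the best
#' validation correlation are restored.
#'
#' @param encoded An \linkS4class{EncodedRNASet} (one or both species).
#' @param targets Named numeric vector of consensus half-life scores.
#' @param folds Named integer fold vector, or a list of per-species fold
#'   vectors as from \code{\link{assignHomologyFolds}}.
#' @param test_fold Fold held out entirely (never seen).
#' @param val_fold Validation fold (default: the fold after
#'   \code{test_fold}).
#' @param hyper Hyperparameters.
#' @param seed Master seed; fans out to weight init, batch order and
#'   dropout.
#' @param replicate Replicate index (shifts the derived seed).
#' @param max_epochs Epoch cap.
#' @param verbose Print per-epoch validation correlations.
#' @return A trained \linkS4class{SalukiModel}; \code{x@log} records
#'   per-epoch validation correlations, the best epoch, and the target
#'   scaling.
#' @export
trainSaluki <- function(encoded, targets, folds, test_fold,
                        val_fold = NULL, hyper = salukiHyperparams(),
                        seed = 1L, replicate = 1L, max_epochs = 100L,
                        verbose = FALSE) {
  stopifnot(is(encoded, "EncodedRNASet"),
            encoded@Lmax == hyper$L_max)
  if (is.list(folds)) folds <- do.call(c, unname(folds))
  ids <- encoded@geneId
  sp_tags <- encoded@species
  keep <- ids %in% names(targets) & ids %in% names(folds)
  if (!all(keep)) {
    encoded <- new("EncodedRNASet", tensors = encoded@tensors[keep],
                   trueLength = encoded@trueLength[keep],
                   species = sp_tags[keep], geneId = ids[keep],
                   Lmax = encoded@Lmax)
    ids <- encoded@geneId; sp_tags <- encoded@species
  }
  fold_of <- folds[ids]
  if (is.null(val_fold)) val_fold <- test_fold %% max(folds) + 1L
  y <- targets[ids]
  scale_by_sp <- list()
  for (sp in unique(sp_tags)) {
    sel <- sp_tags == sp
    mu <- mean(y[sel]); sdv <- stats::sd(y[sel])
    if (is.na(sdv) || sdv == 0) stop("zero-variance target for ", sp)
    y[sel] <- (y[sel] - mu) / sdv
    scale_by_sp[[sp]] <- c(mean = mu, sd = sdv)
  }
  train_idx <- which(!fold_of %in% c(test_fold, val_fold))
  val_idx <- which(fold_of == val_fold)
  if (!length(train_idx) || !length(val_idx))
    stop("empty training or validation split")

  seeds <- .childSeeds(seed, 2L * replicate)
  seed_init <- seeds[2L * replicate - 1L]
  seed_stream <- seeds[2L * replicate]
  model <- buildSaluki(hyper, seed = seed_init)
  params <- model@params
  bnStats <- model@bnStats
  adam <- .adamInit(params)
  l2n <- .l2Names(params)
  species_list <- unique(sp_tags[train_idx])
  val_r_log <- numeric(0)
  best <- list(r = -Inf, params = params, bnStats = bnStats, epoch = 0L)

  set.seed(seed_stream)  # batch order + dropout stream
  for (epoch in seq_len(max_epochs)) {
    batches_by_sp <- lapply(species_list, function(sp) {
      idx <- train_idx[sp_tags[train_idx] == sp]
      idx <- sample(idx)
      split(idx, ceiling(seq_along(idx) / hyper$batch))
    })
    names(batches_by_sp) <- species_list
    n_steps <- max(vapply(batches_by_sp, length, integer(1)))
    for (step in seq_len(n_steps)) {
      for (sp in species_list) {
        bl <- batches_by_sp[[sp]]
        idx <- bl[[(step - 1L) %% length(bl) + 1L]]  # recycle smaller species
        B <- length(idx)
        if (hyper$augment_shift > 0L) {
          shifts <- sample(-hyper$augment_shift:hyper$augment_shift, B,
                           replace = TRUE)
          Xb <- .stackTensors(lapply(seq_len(B), function(q)
            .shiftTensor(encoded@tensors[[idx[q]]], shifts[q])),
            seq_len(B))
        } else {
          Xb <- .stackTensors(encoded@tensors, idx)
        }
        fw <- .salukiForward(params, hyper, Xb, B, sp, training = TRUE,
                             bnStats = bnStats)
        bnStats <- fw$bnStats
        resid <- fw$pred - y[idx]
        if (any(!is.finite(resid)))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        dpred <- 2 * resid / B
        grads <- .salukiBackward(params, hyper, fw$caches, dpred)
        upd <- .adamStep(params, grads, adam, hyper$lr, hyper$beta1,
                         hyper$beta2, hyper$clip_norm, hyper$l2, l2n)
        params <- upd$params
        adam <- upd$state
      }
    }
    ## validation correlation, averaged over the species present
    tmp_model <- new("SalukiModel", params = params, hyper = hyper,
                     bnStats = bnStats, log = list())
    rs <- vapply(species_list, function(sp) {
      vi <- val_idx[sp_tags[val_idx] == sp]
      if (length(vi) < 3L) return(NA_real_)
      p <- .predictTensors(tmp_model, encoded@tensors[vi], sp)
      .safeCor(p, y[vi])
    }, numeric(1))
    vr <- mean(rs, na.rm = TRUE)
    if (is.nan(vr)) stop("validation correlation undefined")
    val_r_log <- c(val_r_log, vr)
    if (verbose)
      message(sprintf("epoch %d: validation r = %.4f", epoch, vr))
    if (vr > best$r)
      best <- list(r = vr, params = params, bnStats = bnStats,
                   epoch = epoch)
    if (epoch - best$epoch >= hyper$patience) break
  }
  new("SalukiModel", params = best$params, hyper = hyper,
      bnStats = best$bnStats,
      log = list(val_r = val_r_log, best_epoch = best$epoch,
                 best_val_r = best$r, target_scale = scale_by_sp,
                 test_fold = test_fold, val_fold = val_fold,
                 replicate = replicate, seed = seed))
}

#' Train a fold-by-replicate ensemble
#'
#' @param encoded,targets,folds,hyper,seed,max_epochs See
#'   \code{\link{trainSaluki}}.
#' @param test_folds Folds to hold out in turn (default all).
#' @param replicates Replicate indices per fold (default 1:5).
#' @param verbose Passed through.
#' @return A \linkS4class{SalukiEnsemble}.
#' @export
trainSalukiEnsemble <- function(encoded, targets, folds,
                                test_folds = NULL, replicates = 1:5,
                                hyper = salukiHyperparams(), seed = 1L,
                                max_epochs = 100L, verbose = FALSE) {
  fold_vec <- if (is.list(folds)) do.call(c, unname(folds)) else folds
  if (is.null(test_folds)) test_folds <- sort(unique(fold_vec))
  grid <- expand.grid(fold = test_folds, replicate = replicates)
  members <- lapply(seq_len(nrow(grid)), function(i)
    trainSaluki(encoded, targets, folds, test_fold = grid$fold[i],
                hyper = hyper, seed = seed, replicate = grid$replicate[i],
                max_epochs = max_epochs, verbose = verbose))
  new("SalukiEnsemble", members = members,
      fold = as.integer(grid$fold), replicate = as.integer(grid$replicate),
      folds = if (is.list(folds)) folds else list(all = folds),
      validationR = vapply(members, function(m) m@log$best_val_r,
                           numeric(1)))
}

#' Ensemble prediction
#'
#' In \code{"heldout"} mode each gene is predicted by the replicates whose
#' held-out test fold contains it (the honest cross-validated prediction);
#' in \code{"external"} mode (third-party sequences) predictions from all
#' members are averaged.
#'
#' @param ensemble A \linkS4class{SalukiEnsemble}.
#' @param encoded An \linkS4class{EncodedRNASet}.
#' @param mode \code{"heldout"} or \code{"external"}.
#' @param species Head selection (default: per-mRNA tags).
#' @param allow_partial Permit an incomplete ensemble in external mode.
#' @return Named numeric predictions.
#' @export
ensemblePredict <- function(ensemble, encoded,
                            mode = c("heldout", "external"),
                            species = NULL, allow_partial = FALSE) {
  mode <- match.arg(mode)
  if (mode == "external") {
    fold_vec <- do.call(c, unname(ensemble@folds))
    expect <- length(unique(fold_vec)) * length(unique(ensemble@replicate))
    if (length(ensemble@members) < expect && !allow_partial)
      stop("incomplete ensemble (", length(ensemble@members), "/", expect,
           " members); use allow_partial = TRUE to override")
    preds <- vapply(ensemble@members, function(m)
      predictSaluki(m, encoded, species = species),
      numeric(length(encoded@tensors)))
    out <- rowMeans(matrix(preds, ncol = length(ensemble@members)))
    names(out) <- encoded@geneId
    return(out)
  }
  fold_vec <- do.call(c, unname(ensemble@folds))
  gene_fold <- fold_vec[encoded@geneId]
  if (anyNA(gene_fold))
    stop("held-out mode requires every gene to carry a fold assignment")
  out <- stats::setNames(rep(NA_real_, length(encoded@geneId)),
                         encoded@geneId)
  for (f in unique(gene_fold)) {
    sel <- which(gene_fold == f)
    mem <- which(ensemble@fold == f)
    if (!length(mem)) stop("no trained members for fold ", f)
    sub <- new("EncodedRNASet", tensors = encoded@tensors[sel],
               trueLength = encoded@trueLength[sel],
               species = encoded@species[sel],
               geneId = encoded@geneId[sel], Lmax = encoded@Lmax)
    pr <- vapply(ensemble@members[mem], function(m)
      predictSaluki(m, sub, species = species), numeric(length(sel)))
    out[sel] <- rowMeans(matrix(pr, ncol = length(mem)))
  }
  out
}
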