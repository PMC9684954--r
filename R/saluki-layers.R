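## Internal neural-network primitives for the half-life regressor.
## All batched sequence tensors use a channels x positions layout: a batch
## of B sequences of length L with C channels is a C x (B*L) matrix whose
## column (b-1)*L + t holds position t of sequence b. This makes the
## convolution tap gathers contiguous column subsets and lets per-channel
## affine parameters broadcast by native recycling. Backward functions
## follow the convention grad-in = d loss / d output.

.LN_EPS <- 1e-3
.BN_EPS <- 1e-3
.BN_MOMENTUM <- 0.9

## ---- 1D convolution, 'same' padding, as a sum of per-tap GEMMs -------------

## Column indices into the zero-padded batch matrix for each of the k
## taps. Padded layout: per sequence, (L + k - 1) columns; padded column
## t + j - 1 holds input position t + j - 1 - (k-1)/2 of output position t.
.convCols <- function(B, L, k) {
  Lp <- L + k - 1L
  base <- rep((seq_len(B) - 1L) * Lp, each = L) + seq_len(L)
  lapply(seq_len(k), function(j) base + (j - 1L))
}

.convPad <- function(X, B, L, k) {
  Cin <- nrow(X)
  p <- (k - 1L) %/% 2L
  Lp <- L + k - 1L
  Xp <- matrix(0, Cin, B * Lp)
  dest <- rep((seq_len(B) - 1L) * Lp, each = L) + p + seq_len(L)
  Xp[, dest] <- X
  Xp
}

## W is a (k*Cin) x Cout matrix (tap-major row blocks), b a length-Cout
## vector. X is Cin x (B*L); the result is Cout x (B*L).
.convForward <- function(X, W, b, B, L, k) {
  Cin <- nrow(X)
  Xp <- .convPad(X, B, L, k)
  cols <- .convCols(B, L, k)
  Z <- NULL
  for (j in seq_len(k)) {
    Wj <- W[((j - 1L) * Cin + 1L):(j * Cin), , drop = FALSE]
    Zj <- crossprod(Wj, Xp[, cols[[j]], drop = FALSE])
    Z <- if (is.null(Z)) Zj else Z + Zj
  }
  Z + b
}

.convBackward <- function(dZ, X, W, B, L, k) {
  Cin <- nrow(X)
  p <- (k - 1L) %/% 2L
  Lp <- L + k - 1L
  Xp <- .convPad(X, B, L, k)
  cols <- .convCols(B, L, k)
  dW <- matrix(0, k * Cin, ncol(W))
  db <- rowSums(dZ)
  dXp <- matrix(0, Cin, B * Lp)
  for (j in seq_len(k)) {
    rows_ <- ((j - 1L) * Cin + 1L):(j * Cin)
    cj <- cols[[j]]
    dW[rows_, ] <- tcrossprod(Xp[, cj, drop = FALSE], dZ)
    dXp[, cj] <- dXp[, cj, drop = FALSE] +
      W[rows_, , drop = FALSE] %*% dZ
  }
  src <- rep((seq_len(B) - 1L) * Lp, each = L) + p + seq_len(L)
  list(dX = dXp[, src, drop = FALSE], dW = dW, db = db)
}

## ---- max pooling (width 2) -------------------------------------------------

.poolForward <- function(X, B, L) {
  odd <- seq(1L, B * L, by = 2L)
  A <- X[, odd, drop = FALSE]
  Bm <- X[, odd + 1L, drop = FALSE]
  mask <- A >= Bm                     # ties resolved to the earlier position
  list(out = pmax(A, Bm), mask = mask)
}

.poolBackward <- function(dOut, mask, B, L) {
  dX <- matrix(0, nrow(dOut), B * L)
  odd <- seq(1L, B * L, by = 2L)
  dX[, odd] <- dOut * mask
  dX[, odd + 1L] <- dOut * (!mask)
  dX
}

## ---- layer normalization (per position, across channels) -------------------

.lnForward <- function(X, gamma, beta) {
  C <- nrow(X)
  mu <- colMeans(X)
  xc <- X - rep(mu, each = C)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * rep(inv, each = C)
  out <- xhat * gamma + beta          # per-channel, recycles down columns
  list(out = out, xhat = xhat, inv = inv)
}

.lnBackward <- function(dOut, cache, gamma) {
  C <- nrow(dOut)
  xhat <- cache$xhat
  dgamma <- rowSums(dOut * xhat)
  dbeta <- rowSums(dOut)
  dxh <- dOut * gamma
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * xhat)
  dX <- (dxh - rep(m1, each = C) - xhat * rep(m2, each = C)) *
    rep(cache$inv, each = C)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- batch normalization (over the batch, per unit; B x C layout) ----------

.bnForward <- function(X, gamma, beta, stats, training) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    stats$mean <- .BN_MOMENTUM * stats$mean + (1 - .BN_MOMENTUM) * mu
    stats$var <- .BN_MOMENTUM * stats$var + (1 - .BN_MOMENTUM) * v
  } else {
    mu <- stats$mean
    v <- stats$var
    xc <- sweep(X, 2, mu)
  }
  inv <- 1 / sqrt(v + .BN_EPS)
  xhat <- sweep(xc, 2, inv, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, inv = inv, stats = stats)
}

.bnBackward <- function(dOut, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxh <- sweep(dOut, 2, gamma, "*")
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * xhat)
  dX <- sweep(sweep(dxh, 2, m1) - sweep(xhat, 2, m2, "*"),
              2, cache$inv, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- gated recurrent unit, running 3' -> 5' --------------------------------

## X: C x (B*T); steps processed in order T, T-1, ..., 1 so the final
## hidden state summarizes the sequence at its 5' end. Gate layout within
## the 3h columns: update (z), reset (r), candidate (n); the candidate's
## recurrent term is gated after its bias (two bias vectors). The
## per-step state matrices are B x h.
.gruForward <- function(X, Wx, Wh, bx, bh, B, T) {
  hdim <- ncol(Wh) / 3L
  hprev <- matrix(0, B, hdim)
  steps <- vector("list", T)
  order_ <- rev(seq_len(T))
  iz <- seq_len(hdim); ir <- hdim + iz; in_ <- 2L * hdim + iz
  for (s in seq_len(T)) {
    t <- order_[s]
    xt <- t(X[, (seq_len(B) - 1L) * T + t, drop = FALSE])
    gx <- sweep(xt %*% Wx, 2, bx, "+")
    gh <- sweep(hprev %*% Wh, 2, bh, "+")
    z <- .logistic(gx[, iz, drop = FALSE] + gh[, iz, drop = FALSE])
    r <- .logistic(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
    nh <- gh[, in_, drop = FALSE]
    n <- tanh(gx[, in_, drop = FALSE] + r * nh)
    hnew <- z * hprev + (1 - z) * n
    steps[[s]] <- list(t = t, xt = xt, hprev = hprev, z = z, r = r,
                       n = n, nh = nh)
    hprev <- hnew
  }
  list(out = hprev, steps = steps)
}

.gruBackward <- function(dh, cache, Wx, Wh, B, T) {
  hdim <- ncol(dh)
  iz <- seq_len(hdim); ir <- hdim + iz; in_ <- 2L * hdim + iz
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  dbx <- numeric(ncol(Wx)); dbh <- numeric(ncol(Wh))
  dX <- matrix(0, nrow(Wx), B * T)
  for (s in rev(seq_along(cache$steps))) {
    st <- cache$steps[[s]]
    dz <- dh * (st$hprev - st$n)
    dn <- dh * (1 - st$z)
    dnpre <- dn * (1 - st$n^2)
    dr <- dnpre * st$nh
    dnh <- dnpre * st$r
    dzpre <- dz * st$z * (1 - st$z)
    drpre <- dr * st$r * (1 - st$r)
    dgx <- cbind(dzpre, drpre, dnpre)
    dgh <- cbind(dzpre, drpre, dnh)
    dWx <- dWx + crossprod(st$xt, dgx)
    dWh <- dWh + crossprod(st$hprev, dgh)
    dbx <- dbx + colSums(dgx)
    dbh <- dbh + colSums(dgh)
    dX[, (seq_len(B) - 1L) * T + st$t] <- Wx %*% t(dgx)
    dh <- dh * st$z + tcrossprod(dgh, Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, dbx = dbx, dbh = dbh)
}

## ---- optimizer -------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

## Global-norm gradient clipping followed by an Adam update. `l2_names`
## marks the weight matrices carrying the L2 penalty (added to the raw
## gradient before clipping, matching a loss-side penalty).
.adamStep <- function(params, grads, state, lr, beta1, beta2, clip_norm,
                      l2 = 0, l2_names = character(), eps = 1e-7) {
  for (nm in l2_names)
    if (!is.null(grads[[nm]]))
      grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(gnorm) && gnorm > clip_norm) {
    sc <- clip_norm / gnorm
    grads <- lapply(grads, function(g) g * sc)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state, gnorm = gnorm)
}
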