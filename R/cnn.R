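## Internal implementation of the small convolutional network.
##
## Input: 7 x 4 x L tensors. Convolution: nF kernels of 2 x 2 x L with
## shape-preserving (bottom/right zero) padding and ReLU; max pooling
## 2 x 2 at stride 1, also shape preserving; flatten to 28 * nF units
## (56 with two filters); inverted dropout on the flattened layer during
## training; dense softmax over two classes. Trained with cross-entropy
## and Adam. The whole network has a few hundred parameters, so plain
## matrix arithmetic is entirely adequate.

.GRID_CELLS <- 28L  # 7 x 4

# For grid cell k (column-major: k = (c-1)*7 + r), the four cells covered
# by a 2x2 window anchored at (r, c); 0 marks padding.
.gridNeighbors <- function() {
  nbr <- matrix(0L, .GRID_CELLS, 4L)
  for (k in seq_len(.GRID_CELLS)) {
    r <- (k - 1L) %% 7L + 1L
    c <- (k - 1L) %/% 7L + 1L
    nbr[k, 1] <- k
    if (r < 7L) nbr[k, 2] <- k + 1L
    if (c < 4L) nbr[k, 3] <- k + 7L
    if (r < 7L && c < 4L) nbr[k, 4] <- k + 8L
  }
  nbr
}

# im2col for a batch: X is nb x (28 * L) (cell-major within layer).
# Returns (nb * 28) x (4 * L), rows ordered cell-major then sample.
.im2col <- function(X, L, nbr) {
  nb <- nrow(X)
  Xz <- cbind(X, 0)
  zcol <- ncol(Xz)
  out <- matrix(0, nb * .GRID_CELLS, 4L * L)
  for (l in seq_len(L)) {
    off <- (l - 1L) * .GRID_CELLS
    for (s in 1:4) {
      src <- ifelse(nbr[, s] > 0L, off + nbr[, s], zcol)
      out[, (l - 1L) * 4L + s] <- as.vector(Xz[, src])
    }
  }
  out
}

.cnnForward <- function(X, w, L, nbr, dropMask = NULL) {
  nb <- nrow(X)
  nF <- ncol(w$Wc)
  Xcol <- .im2col(X, L, nbr)
  Zc <- sweep(Xcol %*% w$Wc, 2, w$bc, `+`)       # (nb*28) x nF
  A <- pmax(Zc, 0)
  D <- matrix(0, nb, .GRID_CELLS * nF)
  argPool <- vector("list", nF)
  for (f in seq_len(nF)) {
    Am <- matrix(A[, f], nb, .GRID_CELLS)
    Az <- cbind(Am, -Inf)
    zcol <- ncol(Az)
    best <- Az[, ifelse(nbr[, 1] > 0L, nbr[, 1], zcol)]
    arg <- matrix(1L, nb, .GRID_CELLS)
    for (s in 2:4) {
      cand <- Az[, ifelse(nbr[, s] > 0L, nbr[, s], zcol)]
      upd <- cand > best
      best[upd] <- cand[upd]
      arg[upd] <- s
    }
    argPool[[f]] <- arg
    D[, (f - 1L) * .GRID_CELLS + seq_len(.GRID_CELLS)] <- best
  }
  if (!is.null(dropMask)) D <- D * dropMask
  logits <- sweep(D %*% w$Wd, 2, w$bd, `+`)
  ex <- exp(logits - apply(logits, 1, max))
  probs <- ex / rowSums(ex)
  list(Xcol = Xcol, Zc = Zc, argPool = argPool, D = D, probs = probs)
}

.cnnBackward <- function(fwd, w, Yhot, L, nbr) {
  nb <- nrow(Yhot)
  nF <- ncol(w$Wc)
  G <- (fwd$probs - Yhot) / nb
  dWd <- crossprod(fwd$D, G)
  dbd <- colSums(G)
  dD <- G %*% t(w$Wd)
  if (!is.null(fwd$dropMask)) dD <- dD * fwd$dropMask
  dZ <- matrix(0, nb * .GRID_CELLS, nF)
  for (f in seq_len(nF)) {
    dP <- dD[, (f - 1L) * .GRID_CELLS + seq_len(.GRID_CELLS)]
    arg <- fwd$argPool[[f]]
    dAm <- matrix(0, nb, .GRID_CELLS)
    # the source map o -> nbr[o, s] is injective for each slot s,
    # so each slot scatters without collisions
    for (s in 1:4) {
      valid <- which(nbr[, s] > 0L)
      contrib <- dP[, valid, drop = FALSE] *
        (arg[, valid, drop = FALSE] == s)
      dAm[, nbr[valid, s]] <- dAm[, nbr[valid, s]] + contrib
    }
    dZ[, f] <- as.vector(dAm) * (fwd$Zc[, f] > 0)
  }
  dWc <- crossprod(fwd$Xcol, dZ)
  dbc <- colSums(dZ)
  list(Wc = dWc, bc = dbc, Wd = dWd, bd = dbd)
}

.adamStep <- function(w, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

# Train on X (n x 28L flattened tensors) and binary labels y (factor).
.cnnTrain <- function(X, y, config, seed) {
  L <- ncol(X) / .GRID_CELLS
  stopIfNot(L == round(L), "tensor depth inconsistent with the 7x4 grid")
  L <- as.integer(L)
  nbr <- .gridNeighbors()
  nF <- config@nFilters
  lev <- levels(y)
  n <- nrow(X)
  flat <- .GRID_CELLS * nF

  withSeed(seed, {
    w <- list(
      Wc = matrix(stats::rnorm(4L * L * nF, sd = 0.1), 4L * L, nF),
      bc = rep(0, nF),
      Wd = matrix(stats::rnorm(flat * 2L, sd = 0.1), flat, 2L),
      bd = rep(0, 2)
    )
    state <- list(m = lapply(w, function(z) z * 0),
                  v = lapply(w, function(z) z * 0))
    Yhot <- cbind(as.numeric(y == lev[1]), as.numeric(y == lev[2]))
    p <- config@dropoutRate
    t <- 0L
    for (ep in seq_len(config@epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- perm[start:min(start + config@batchSize - 1L, n)]
        nb <- length(idx)
        mask <- if (p > 0) {
          matrix(stats::rbinom(nb * flat, 1L, 1 - p), nb, flat) / (1 - p)
        } else NULL
        fwd <- .cnnForward(X[idx, , drop = FALSE], w, L, nbr, mask)
        fwd$dropMask <- mask
        g <- .cnnBackward(fwd, w, Yhot[idx, , drop = FALSE], L, nbr)
        t <- t + 1L
        upd <- .adamStep(w, g, state, config@learningRate, t)
        w <- upd$w
        state <- upd$state
      }
    }
    list(weights = w, classLevels = lev, flattenLength = flat,
         inputDepth = L)
  })
}

.cnnPredict <- function(model, X) {
  nbr <- .gridNeighbors()
  fwd <- .cnnForward(X, model@weights, model@inputDepth, nbr, NULL)
  factor(model@classLevels[max.col(fwd$probs, ties.method = "first")],
         levels = model@classLevels)
}
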