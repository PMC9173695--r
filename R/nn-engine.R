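# Vectorised 1D-CNN primitives on N x L x C arrays.
#
# Convolutions are evaluated as K shifted matrix products against a
# zero-padded input (length-preserving "same" padding at stride 1; larger
# strides subsample the stride-1 output grid), so all heavy lifting is BLAS.
# Memory layout note: matrix(X, nrow = N * L) on an N x L x C array yields an
# (N*L) x C matrix because the channel index varies slowest; the same fact
# makes flatten() consistent between forward and backward passes.

conv1d_forward <- function(X, W, b, stride = 1L, cache = FALSE) {
  d <- dim(X); N <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  P <- (K - 1L) %/% 2L
  Xp <- array(0, c(N, L + 2L * P, Cin))
  Xp[, P + seq_len(L), ] <- X
  Ymat <- matrix(b, nrow = N * L, ncol = Cout, byrow = TRUE)
  for (k in seq_len(K)) {
    Mk <- matrix(Xp[, k:(k + L - 1L), , drop = FALSE], nrow = N * L)
    Ymat <- Ymat + Mk %*% matrix(W[k, , ], nrow = Cin)
  }
  Y <- array(Ymat, c(N, L, Cout))
  if (stride > 1L) Y <- Y[, seq(1L, L, by = stride), , drop = FALSE]
  if (cache) list(Y = Y, Xp = Xp, L = L) else Y
}

# gradient/multiplier propagation to the conv input; dY on the strided grid
conv1d_backward_input <- function(dY, W, L, stride = 1L) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  N <- dim(dY)[1]
  if (stride > 1L) {
    full <- array(0, c(N, L, Cout))
    full[, seq(1L, L, by = stride), ] <- dY
    dY <- full
  }
  P <- (K - 1L) %/% 2L
  dYmat <- matrix(dY, nrow = N * L)
  dXp <- array(0, c(N, L + 2L * P, Cin))
  for (k in seq_len(K)) {
    contrib <- array(dYmat %*% t(matrix(W[k, , ], nrow = Cin)),
                     c(N, L, Cin))
    dXp[, k:(k + L - 1L), ] <- dXp[, k:(k + L - 1L), , drop = FALSE] +
      contrib
  }
  dXp[, P + seq_len(L), , drop = FALSE]
}

conv1d_backward_params <- function(dY, Xp, L, K, Cin, Cout, stride = 1L) {
  N <- dim(dY)[1]
  if (stride > 1L) {
    full <- array(0, c(N, L, Cout))
    full[, seq(1L, L, by = stride), ] <- dY
    dY <- full
  }
  dYmat <- matrix(dY, nrow = N * L)
  gW <- array(0, c(K, Cin, Cout))
  for (k in seq_len(K)) {
    Mk <- matrix(Xp[, k:(k + L - 1L), , drop = FALSE], nrow = N * L)
    gW[k, , ] <- crossprod(Mk, dYmat)
  }
  list(W = gW, b = colSums(dYmat))
}

maxpool_forward <- function(X, cache = FALSE) {
  d <- dim(X); L <- d[2]
  J <- L %/% 2L
  A <- X[, seq(1L, 2L * J, by = 2L), , drop = FALSE]
  B <- X[, seq(2L, 2L * J, by = 2L), , drop = FALSE]
  Y <- pmax(A, B)
  if (cache) list(Y = Y, first = A >= B, L = L) else Y
}

maxpool_backward <- function(dY, first, L) {
  d <- dim(dY); N <- d[1]; J <- d[2]; C <- d[3]
  dX <- array(0, c(N, L, C))
  dX[, seq(1L, 2L * J, by = 2L), ] <- dY * first
  dX[, seq(2L, 2L * J, by = 2L), ] <- dY * !first
  dX
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

dropout_mask <- function(dims, rate) {
  array(stats::rbinom(prod(dims), 1L, 1 - rate) / (1 - rate), dims)
}

softmax2 <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - m); e2 <- exp(logits[, 2L] - m)
  cbind(e1, e2, deparse.level = 0) / (e1 + e2)
}

flatten3 <- function(X) matrix(X, nrow = dim(X)[1])

unflatten3 <- function(M, L, C) array(M, c(nrow(M), L, C))

# pooled lengths after each conv block
layer_lengths <- function(config) {
  L <- config$input_length
  out <- integer(config$n_conv_blocks)
  for (i in seq_len(config$n_conv_blocks)) {
    L <- ceiling(L / config$stride) %/% config$pool_size
    out[i] <- L
  }
  out
}

# Full forward pass. X: N x input_length x 4.
# training = TRUE applies inverted dropout (caller controls the RNG state).
# keep = TRUE returns every intermediate needed for backprop / attribution.
nn_forward <- function(params, config, X, training = FALSE, keep = FALSE) {
  cache <- list()
  H <- X
  for (i in seq_len(config$n_conv_blocks)) {
    cv <- conv1d_forward(H, params$conv[[i]]$W, params$conv[[i]]$b,
                         stride = config$stride, cache = keep)
    Z <- if (keep) cv$Y else cv
    A <- relu(Z)
    pl <- maxpool_forward(A, cache = keep)
    Pl <- if (keep) pl$Y else pl
    if (training && config$conv_dropout > 0) {
      mask <- dropout_mask(dim(Pl), config$conv_dropout)
      Pl <- Pl * mask
      if (keep) cache[[paste0("mask", i)]] <- mask
    }
    if (keep) {
      cache[[paste0("conv", i)]] <- cv
      cache[[paste0("z", i)]] <- Z
      cache[[paste0("pool", i)]] <- pl
    }
    H <- Pl
  }
  Fmat <- flatten3(H)
  if (keep) cache$flat <- Fmat
  Hd <- Fmat
  for (j in seq_along(config$dense_units)) {
    Zd <- sweep(Hd %*% params$dense[[j]]$W, 2L, params$dense[[j]]$b, "+")
    Ad <- relu(Zd)
    if (training && config$dense_dropout > 0) {
      mask <- matrix(stats::rbinom(length(Ad), 1L, 1 - config$dense_dropout) /
                       (1 - config$dense_dropout), nrow = nrow(Ad))
      Ad <- Ad * mask
      if (keep) cache[[paste0("dmask", j)]] <- mask
    }
    if (keep) {
      cache[[paste0("zd", j)]] <- Zd
      cache[[paste0("in_d", j)]] <- Hd
    }
    Hd <- Ad
  }
  logits <- sweep(Hd %*% params$out$W, 2L, params$out$b, "+")
  probs <- softmax2(logits)
  if (keep) {
    cache$top <- Hd
    list(probs = probs, logits = logits, cache = cache)
  } else {
    list(probs = probs, logits = logits)
  }
}

# Backprop of mean cross-entropy; y is a 0/1 vector (1 = class index 2).
nn_backward <- function(params, config, fw, X, y) {
  N <- dim(X)[1]
  Y <- cbind(1 - y, y)
  dlogits <- (fw$probs - Y) / N
  g <- list(conv = vector("list", config$n_conv_blocks),
            dense = vector("list", length(config$dense_units)))
  g$out <- list(W = crossprod(fw$cache$top, dlogits), b = colSums(dlogits))
  dH <- tcrossprod(dlogits, params$out$W)
  for (j in rev(seq_along(config$dense_units))) {
    mask <- fw$cache[[paste0("dmask", j)]]
    if (!is.null(mask)) dH <- dH * mask
    dZ <- dH * (fw$cache[[paste0("zd", j)]] > 0)
    g$dense[[j]] <- list(W = crossprod(fw$cache[[paste0("in_d", j)]], dZ),
                         b = colSums(dZ))
    dH <- tcrossprod(dZ, params$dense[[j]]$W)
  }
  lens <- layer_lengths(config)
  nb <- config$n_conv_blocks
  dP <- unflatten3(dH, lens[nb], config$filters_per_block)
  for (i in rev(seq_len(nb))) {
    mask <- fw$cache[[paste0("mask", i)]]
    if (!is.null(mask)) dP <- dP * mask
    pl <- fw$cache[[paste0("pool", i)]]
    dA <- maxpool_backward(dP, pl$first, dim(fw$cache[[paste0("z", i)]])[2])
    dZ <- dA * (fw$cache[[paste0("z", i)]] > 0)
    cv <- fw$cache[[paste0("conv", i)]]
    Cin <- dim(params$conv[[i]]$W)[2]
    g$conv[[i]] <- conv1d_backward_params(
      dZ, cv$Xp, cv$L, config$kernel_size, Cin, config$filters_per_block,
      stride = config$stride)
    if (i > 1L) {
      dX <- conv1d_backward_input(dZ, params$conv[[i]]$W, cv$L,
                                  stride = config$stride)
      dP <- dX
    }
  }
  g
}
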