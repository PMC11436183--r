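# Hand-rolled neural-network layer primitives (forward + backward) used by
# the capsule front-ends. Everything operates on plain base-R arrays:
#   epochs          (B, C, T)
#   temporal maps   (B, M, T)        M feature maps
#   4-D conv stacks (B, F, C, T) or (B, F, H, W)
# All backward passes are validated against central finite differences in
# the test suite; layouts below exploit R's column-major order so that a
# (B, M, T) array flattens to a (B*M, T) matrix with rows ordered
# b-fastest-within-m.

.pad_cols <- function(Xm, left, right) {
  n <- nrow(Xm)
  cbind(matrix(0, n, left), Xm, matrix(0, n, right))
}

## ---- temporal convolution, kernel (1, TI), F1 filters, same padding ----
## in (B, C, T) -> out (B, F1, C, T)

.conv_time_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; C <- d[2]; T <- d[3]
  F1 <- nrow(W); TI <- ncol(W)
  padL <- (TI - 1L) %/% 2L; padR <- TI - 1L - padL
  Xp <- .pad_cols(matrix(X, B * C, T), padL, padR)
  M <- matrix(0, B * C * T, TI)
  for (k in seq_len(TI)) M[, k] <- as.vector(Xp[, k:(k + T - 1L)])
  Y0 <- sweep(M %*% t(W), 2L, b, "+")
  Y <- aperm(array(Y0, c(B, C, T, F1)), c(1L, 4L, 2L, 3L))
  list(out = Y, cache = list(M = M, W = W, dims = d, padL = padL, padR = padR))
}

.conv_time_bwd <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; C <- d[2]; T <- d[3]
  W <- cache$W; F1 <- nrow(W); TI <- ncol(W)
  dY0 <- matrix(aperm(dY, c(1L, 3L, 4L, 2L)), B * C * T, F1)
  dW <- t(dY0) %*% cache$M
  db <- colSums(dY0)
  dM <- dY0 %*% W
  dXp <- matrix(0, B * C, T + TI - 1L)
  for (k in seq_len(TI)) {
    dXp[, k:(k + T - 1L)] <- dXp[, k:(k + T - 1L)] + matrix(dM[, k], B * C, T)
  }
  dX <- array(dXp[, (cache$padL + 1L):(cache$padL + T), drop = FALSE], d)
  list(dX = dX, dW = dW, db = db)
}

## ---- spatial depthwise convolution, kernel (C, 1), multiplier D ----
## in (B, F1, C, T) -> out (B, F1*D, T); collapses the channel axis.
## W: (F1, D, C); output map m = (f-1)*D + d.

.conv_space_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; F1 <- d[2]; C <- d[3]; T <- d[4]
  D <- dim(W)[2]
  Y <- array(0, c(B, F1 * D, T))
  Xf_list <- vector("list", F1)
  for (f in seq_len(F1)) {
    Xf <- matrix(aperm(X[, f, , , drop = FALSE], c(3L, 1L, 4L, 2L)), C, B * T)
    Xf_list[[f]] <- Xf
    Wf <- matrix(W[f, , ], dim(W)[2], C)
    Yf <- Wf %*% Xf
    for (dd in seq_len(D)) {
      m <- (f - 1L) * D + dd
      Y[, m, ] <- matrix(Yf[dd, ], B, T) + b[m]
    }
  }
  list(out = Y, cache = list(Xf = Xf_list, W = W, dims = d))
}

.conv_space_bwd <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; F1 <- d[2]; C <- d[3]; T <- d[4]
  W <- cache$W; D <- dim(W)[2]
  dW <- array(0, dim(W)); db <- numeric(F1 * D)
  dX <- array(0, d)
  for (f in seq_len(F1)) {
    dYf <- matrix(0, D, B * T)
    for (dd in seq_len(D)) {
      m <- (f - 1L) * D + dd
      dYm <- matrix(dY[, m, ], B, T)
      db[m] <- sum(dYm)
      dYf[dd, ] <- as.vector(dYm)
    }
    dW[f, , ] <- dYf %*% t(cache$Xf[[f]])
    dXf <- t(matrix(W[f, , ], D, C)) %*% dYf
    dX[, f, , ] <- aperm(array(dXf, c(C, B, T)), c(2L, 1L, 3L))
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- batch normalization over feature maps (dim 2 of any array) ----

# per-map (dim 2) totals of an array of any rank >= 2
.map_sums <- function(X) {
  d <- dim(X)
  rs <- rowSums(matrix(X, d[1] * d[2], length(X) / (d[1] * d[2])))
  colSums(matrix(rs, d[1], d[2]))
}

# expand a per-map vector so it recycles correctly over (dim1, map, rest)
.map_expand <- function(v, d1) rep(v, each = d1)

.bn_fwd <- function(X, gamma, beta, run_mean, run_var, train,
                    momentum = 0.1, eps = 1e-5) {
  d1 <- dim(X)[1]; M <- dim(X)[2]
  N <- length(X) / M
  if (train) {
    mu <- .map_sums(X) / N
    Xc <- X - .map_expand(mu, d1)
    v <- .map_sums(Xc * Xc) / N
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * N / max(N - 1, 1)
  } else {
    mu <- run_mean
    v <- run_var
    Xc <- X - .map_expand(mu, d1)
  }
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * .map_expand(inv, d1)
  Y <- Xhat * .map_expand(gamma, d1) + .map_expand(beta, d1)
  list(out = Y,
       cache = list(Xhat = Xhat, inv = inv, gamma = gamma, N = N,
                    train = train),
       run_mean = run_mean, run_var = run_var)
}

.bn_bwd <- function(dY, cache) {
  d1 <- dim(dY)[1]
  dXhat <- dY * .map_expand(cache$gamma, d1)
  dgamma <- .map_sums(dY * cache$Xhat)
  dbeta <- .map_sums(dY)
  if (cache$train) {
    N <- cache$N
    s1 <- .map_sums(dXhat)
    s2 <- .map_sums(dXhat * cache$Xhat)
    dX <- (dXhat - .map_expand(s1 / N, d1) -
             cache$Xhat * .map_expand(s2 / N, d1)) * .map_expand(cache$inv, d1)
  } else {
    dX <- dXhat * .map_expand(cache$inv, d1)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- ELU activation ----

.elu_fwd <- function(X) {
  Y <- X
  neg <- X <= 0
  Y[neg] <- exp(X[neg]) - 1
  list(out = Y, cache = Y)
}

.elu_bwd <- function(dY, cache) {
  g <- dY
  neg <- cache <= 0
  g[neg] <- g[neg] * (cache[neg] + 1)
  g
}

## ---- temporal average pooling, width p (truncates trailing remainder) ----

.pool_fwd <- function(X, p) {
  d <- dim(X); B <- d[1]; M <- d[2]; T <- d[3]
  To <- T %/% p; Tc <- To * p
  Xm <- matrix(X, B * M, T)
  Ym <- matrix(0, B * M, To)
  for (i in seq_len(p)) Ym <- Ym + Xm[, seq(i, Tc, by = p), drop = FALSE]
  list(out = array(Ym / p, c(B, M, To)), cache = list(dims = d, p = p))
}

.pool_bwd <- function(dY, cache) {
  d <- cache$dims; p <- cache$p; B <- d[1]; M <- d[2]; T <- d[3]
  To <- T %/% p
  dYm <- matrix(dY, B * M, To) / p
  dXm <- matrix(0, B * M, T)
  for (i in seq_len(p)) dXm[, seq(i, To * p, by = p)] <- dYm
  array(dXm, d)
}

## ---- depthwise temporal convolution, per-map kernel (1, K), same pad ----
## in (B, M, T) -> out (B, M, T); W: (M, K).

.conv_dw_time_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; M <- d[2]; T <- d[3]
  K <- ncol(W)
  padL <- (K - 1L) %/% 2L; padR <- K - 1L - padL
  Xp <- .pad_cols(matrix(X, B * M, T), padL, padR)
  Ym <- matrix(0, B * M, T)
  for (k in seq_len(K)) {
    Ym <- Ym + Xp[, k:(k + T - 1L), drop = FALSE] * rep(W[, k], each = B)
  }
  Ym <- Ym + rep(b, each = B)
  list(out = array(Ym, d), cache = list(Xp = Xp, W = W, dims = d, padL = padL))
}

.conv_dw_time_bwd <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; M <- d[2]; T <- d[3]
  W <- cache$W; K <- ncol(W)
  dYm <- matrix(dY, B * M, T)
  db <- colSums(matrix(rowSums(dYm), B, M))
  dW <- matrix(0, M, K)
  dXp <- matrix(0, B * M, T + K - 1L)
  for (k in seq_len(K)) {
    P <- dYm * cache$Xp[, k:(k + T - 1L), drop = FALSE]
    dW[, k] <- colSums(matrix(rowSums(P), B, M))
    dXp[, k:(k + T - 1L)] <- dXp[, k:(k + T - 1L)] + dYm * rep(W[, k], each = B)
  }
  dX <- array(dXp[, (cache$padL + 1L):(cache$padL + T), drop = FALSE], d)
  list(dX = dX, dW = dW, db = db)
}

## ---- pointwise (1, 1) convolution mixing maps ----
## in (B, M, T) -> out (B, F2, T); W: (F2, M).

.conv_pw_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; M <- d[2]; T <- d[3]
  F2 <- nrow(W)
  Xm <- matrix(aperm(X, c(2L, 1L, 3L)), M, B * T)
  Ym <- sweep(W %*% Xm, 1L, b, "+")
  Y <- aperm(array(Ym, c(F2, B, T)), c(2L, 1L, 3L))
  list(out = Y, cache = list(Xm = Xm, W = W, dims = d))
}

.conv_pw_bwd <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; M <- d[2]; T <- d[3]
  F2 <- nrow(cache$W)
  dYm <- matrix(aperm(dY, c(2L, 1L, 3L)), F2, B * T)
  dW <- dYm %*% t(cache$Xm)
  db <- rowSums(dYm)
  dXm <- t(cache$W) %*% dYm
  dX <- aperm(array(dXm, c(M, B, T)), c(2L, 1L, 3L))
  list(dX = dX, dW = dW, db = db)
}

## ---- depthwise feature-fusion convolution spanning the whole residual ----
## temporal extent: in (B, M, Tr) -> out (B, M); W: (M, Tr).

.conv_fuse_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; M <- d[2]
  Xm <- matrix(X, B * M, d[3])
  Wexp <- W[rep(seq_len(M), each = B), , drop = FALSE]
  Y <- sweep(matrix(rowSums(Xm * Wexp), B, M), 2L, b, "+")
  list(out = Y, cache = list(Xm = Xm, W = W, dims = d))
}

.conv_fuse_bwd <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; M <- d[2]
  dYv <- as.vector(dY)
  db <- colSums(dY)
  dW <- rowsum(cache$Xm * dYv, rep(seq_len(M), each = B))
  dimnames(dW) <- NULL
  Wexp <- cache$W[rep(seq_len(M), each = B), , drop = FALSE]
  list(dX = array(Wexp * dYv, d), dW = dW, db = db)
}

## ---- plain 2-D convolution, square kernel, valid padding, stride ----
## in (B, Cin, H, W) -> out (B, F, Ho, Wo); used only by the traditional
## (square-kernel) capsule front-end of the ablation harness.

.conv2d_fwd <- function(X, W, b, stride) {
  d <- dim(X); B <- d[1]; Cin <- d[2]; H <- d[3]; Wd <- d[4]
  F <- dim(W)[1]; k <- dim(W)[3]
  sh <- stride[1]; sw <- stride[2]
  Ho <- (H - k) %/% sh + 1L; Wo <- (Wd - k) %/% sw + 1L
  if (Ho < 1L || Wo < 1L) {
    .stop_cfg("conv2d kernel %d does not fit input (%d, %d)", k, H, Wd)
  }
  M <- matrix(0, B * Ho * Wo, Cin * k * k)
  col <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) for (cc in seq_len(Cin)) {
    col <- col + 1L
    M[, col] <- as.vector(X[, cc,
                            seq(ki, by = sh, length.out = Ho),
                            seq(kj, by = sw, length.out = Wo), drop = FALSE])
  }
  Wm <- matrix(W, F, Cin * k * k)
  Y0 <- sweep(M %*% t(Wm), 2L, b, "+")
  Y <- aperm(array(Y0, c(B, Ho, Wo, F)), c(1L, 4L, 2L, 3L))
  list(out = Y,
       cache = list(M = M, Wm = Wm, dims = d, dimW = dim(W),
                    stride = stride, Ho = Ho, Wo = Wo))
}

.conv2d_bwd <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; Cin <- d[2]
  F <- cache$dimW[1]; k <- cache$dimW[3]
  sh <- cache$stride[1]; sw <- cache$stride[2]
  Ho <- cache$Ho; Wo <- cache$Wo
  dY0 <- matrix(aperm(dY, c(1L, 3L, 4L, 2L)), B * Ho * Wo, F)
  dWm <- t(dY0) %*% cache$M
  db <- colSums(dY0)
  dM <- dY0 %*% cache$Wm
  dX <- array(0, d)
  col <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) for (cc in seq_len(Cin)) {
    col <- col + 1L
    ii <- seq(ki, by = sh, length.out = Ho)
    jj <- seq(kj, by = sw, length.out = Wo)
    cur <- dX[, cc, ii, jj, drop = FALSE]   # keep dims: Ho or Wo may be 1
    dX[, cc, ii, jj] <- as.vector(cur) + dM[, col]
  }
  list(dX = dX, dW = array(dWm, cache$dimW), db = db)
}

## ---- global average pooling over the two trailing spatial dims ----

.gap_fwd <- function(X) {
  d <- dim(X)
  list(out = apply(X, c(1L, 2L), mean), cache = d)
}

.gap_bwd <- function(dY, dims) {
  n <- dims[3] * dims[4]
  array(rep(as.vector(dY) / n, n), dims)
}
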