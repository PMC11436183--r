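# Self-correlation routing (non-iterative) and the classic iterative
# dynamic-routing baseline. Shapes throughout:
#   U     (B, n_l, d_l)          input capsules
#   W     (n_l, n_out, d_l, d_out)  learnable transformation
#   Bp    (n_l, n_out)           learnable log priors
#   Uhat  (B, n_l, n_out, d_out) per-pair predictions
#   A     (B, n_l, n_l, n_out)   self-correlation (Gram) tensor
#   C     (B, n_l, n_out)        coupling coefficients (softmax over n_out)
#   S/V   (B, n_out, d_out)      routed / squashed class capsules

#' Routing layer weights
#'
#' Seeded initialization of one routing layer: the transformation tensor
#' `W` from fan-in-scaled normals (`sd = 1/sqrt(d_l)`), the log-prior
#' matrix `B` at zero (no initial bias between capsule pairs).
#'
#' @param n_l,d_l input capsule count and dimension.
#' @param n_out,d_out output capsule count and dimension.
#' @param seed integer seed.
#' @return List with arrays `W` `(n_l, n_out, d_l, d_out)` and `B`
#'   `(n_l, n_out)`.
#' @export
routing_weights <- function(n_l, n_out, d_l, d_out, seed = 1) {
  .with_seed(seed, {
    list(W = array(stats::rnorm(n_l * n_out * d_l * d_out),
                   c(n_l, n_out, d_l, d_out)) / sqrt(d_l),
         B = matrix(0, n_l, n_out))
  })
}

#' Predict higher-level capsules
#'
#' Maps every input capsule to a prediction for every output capsule via
#' the learnable transformation:
#' `Uhat[b, i, j, ] = U[b, i, ] %*% W[i, j, , ]`.
#'
#' @param U a `capsule_tensor` or `(B, n_l, d_l)` array.
#' @param W transformation array `(n_l, n_out, d_l, d_out)`.
#' @return Prediction array `(B, n_l, n_out, d_out)`.
#' @export
predict_capsules <- function(U, W) {
  U <- .caps_values(U)
  dW <- dim(W)
  if (length(dim(U)) != 3L || dim(U)[2] != dW[1] || dim(U)[3] != dW[3]) {
    .stop_cfg("capsule shape (%s) does not match W (%s)",
              paste(dim(U), collapse = ","), paste(dW, collapse = ","))
  }
  B <- dim(U)[1]; nl <- dW[1]; no <- dW[2]; dl <- dW[3]; do_ <- dW[4]
  Uhat <- array(0, c(B, nl, no, do_))
  for (i in seq_len(nl)) for (j in seq_len(no)) {
    Uhat[, i, j, ] <- matrix(U[, i, ], B, dl) %*% matrix(W[i, j, , ], dl, do_)
  }
  Uhat
}

.predict_bwd <- function(dUhat, U, W) {
  dW <- dim(W)
  B <- dim(U)[1]; nl <- dW[1]; no <- dW[2]; dl <- dW[3]; do_ <- dW[4]
  gU <- array(0, dim(U)); gW <- array(0, dW)
  for (i in seq_len(nl)) for (j in seq_len(no)) {
    dUh <- matrix(dUhat[, i, j, ], B, do_)
    Ui <- matrix(U[, i, ], B, dl)
    Wij <- matrix(W[i, j, , ], dl, do_)
    gW[i, j, , ] <- t(Ui) %*% dUh
    gU[, i, ] <- matrix(gU[, i, ], B, dl) + dUh %*% t(Wij)
  }
  list(dU = gU, dW = gW)
}

#' Self-correlation tensor
#'
#' The Gram matrix of the predictions for each output capsule, scaled by
#' the capsule dimension:
#' `A[b, , , j] = Uhat[b, , j, ] %*% t(Uhat[b, , j, ]) / scale`, where
#' `scale` is `d_l` (default, the printed form) or `sqrt(d_l)`. `A` is
#' symmetric in its two input-capsule axes by construction.
#'
#' @param Uhat prediction array `(B, n_l, n_out, d_out)`.
#' @param d_l input capsule dimension used for scaling.
#' @param corr_scale `"dl"` or `"sqrt_dl"`.
#' @return Self-correlation array `(B, n_l, n_l, n_out)`.
#' @export
self_correlation <- function(Uhat, d_l, corr_scale = c("dl", "sqrt_dl")) {
  corr_scale <- match.arg(corr_scale)
  if (d_l <= 0) .stop_cfg("`d_l` must be positive")
  scale <- if (corr_scale == "dl") d_l else sqrt(d_l)
  d <- dim(Uhat); B <- d[1]; nl <- d[2]; no <- d[3]; do_ <- d[4]
  A <- array(0, c(B, nl, nl, no))
  for (b in seq_len(B)) for (j in seq_len(no)) {
    Ubj <- matrix(Uhat[b, , j, ], nl, do_)
    A[b, , , j] <- tcrossprod(Ubj) / scale
  }
  A
}

.self_correlation_bwd <- function(dA, Uhat, d_l, corr_scale = "dl") {
  scale <- if (corr_scale == "dl") d_l else sqrt(d_l)
  d <- dim(Uhat); B <- d[1]; nl <- d[2]; no <- d[3]; do_ <- d[4]
  dUhat <- array(0, d)
  for (b in seq_len(B)) for (j in seq_len(no)) {
    G <- matrix(dA[b, , , j], nl, nl)
    Ubj <- matrix(Uhat[b, , j, ], nl, do_)
    dUhat[b, , j, ] <- (G + t(G)) %*% Ubj / scale
  }
  dUhat
}

#' Coupling coefficients from the self-correlation tensor
#'
#' Sums the self-correlation tensor over its second input-capsule axis to
#' obtain per-pair logits, then applies a numerically stabilized softmax
#' across output capsules:
#' `C[b, i, j] = exp(sum_k A[b, i, k, j]) / sum_j' exp(sum_k A[b, i, k, j'])`.
#' Max-subtraction leaves the value unchanged while preventing overflow.
#' Every row sums to 1 over the output-capsule axis.
#'
#' @param A self-correlation array `(B, n_l, n_l, n_out)`.
#' @return Coupling array `(B, n_l, n_out)` with entries in `(0, 1)`.
#' @export
coupling_coefficients <- function(A) {
  if (anyNA(A) || any(!is.finite(A))) {
    stop("coupling_coefficients() requires finite input", call. = FALSE)
  }
  L <- apply(A, c(1L, 2L, 4L), sum)          # (B, nl, no)
  .softmax3_fwd(L)
}

# softmax over dim 3 of (B, nl, no), stabilized by max-subtraction
.softmax3_fwd <- function(L) {
  Lmax <- apply(L, c(1L, 2L), max)
  E <- exp(L - as.vector(Lmax))
  Z <- apply(E, c(1L, 2L), sum)
  E / as.vector(Z)
}

.softmax3_bwd <- function(dC, C) {
  s <- apply(dC * C, c(1L, 2L), sum)
  C * (dC - as.vector(s))
}

# expand softmax-input gradient dL (B, nl, no) back to dA (B, nl, nl, no)
.logits_bwd_toA <- function(dL, nl) {
  d <- dim(dL)
  dA <- array(0, c(d[1], nl, nl, d[3]))
  for (k in seq_len(nl)) dA[, , k, ] <- dL
  dA
}

# S[b,j,e] = sum_i M[b,i,j] * Uhat[b,i,j,e]
.weighted_caps_sum <- function(Uhat, M) {
  d <- dim(Uhat); B <- d[1]; nl <- d[2]; no <- d[3]; do_ <- d[4]
  S <- array(0, c(B, no, do_))
  for (j in seq_len(no)) {
    Uj <- array(Uhat[, , j, ], c(B, nl, do_))
    Mj <- matrix(M[, , j], B, nl)
    S[, j, ] <- apply(Uj * as.vector(Mj), c(1L, 3L), sum)
  }
  S
}

# a[b,i,j] = sum_e Uhat[b,i,j,e] * N[b,j,e]
.caps_agreement <- function(Uhat, N) {
  d <- dim(Uhat); B <- d[1]; nl <- d[2]; no <- d[3]; do_ <- d[4]
  a <- array(0, c(B, nl, no))
  for (j in seq_len(no)) {
    Uj <- array(Uhat[, , j, ], c(B, nl, do_))
    Nj <- matrix(N[, j, ], B, do_)
    # broadcast N over i: recycle (b) within each e-slice
    acc <- matrix(0, B, nl)
    for (e in seq_len(do_)) acc <- acc + matrix(Uj[, , e], B, nl) * Nj[, e]
    a[, , j] <- acc
  }
  a
}

#' Aggregate predictions into output capsules
#'
#' The weighted aggregation
#' `S[b, j, ] = sum_i Uhat[b, i, j, ] * (C[b, i, j] + B[i, j])`: coupling
#' coefficients plus learned log priors weight each prediction. The
#' result is squashed by default so that class-capsule norms lie in
#' `[0, 1)`, as the margin loss and the magnitude-as-probability reading
#' require.
#'
#' @param Uhat prediction array `(B, n_l, n_out, d_out)`.
#' @param C coupling array `(B, n_l, n_out)`.
#' @param B_prior log-prior matrix `(n_l, n_out)`.
#' @param squash_output squash the aggregated capsules (default TRUE).
#' @return A `capsule_tensor` `(B, n_out, d_out)`.
#' @export
route_capsules <- function(Uhat, C, B_prior, squash_output = TRUE) {
  d <- dim(Uhat)
  if (!all(dim(C) == d[c(1, 2, 3)])) {
    .stop_cfg("coupling shape (%s) does not match predictions (%s)",
              paste(dim(C), collapse = ","), paste(d, collapse = ","))
  }
  if (!all(dim(B_prior) == d[c(2, 3)])) {
    .stop_cfg("log-prior shape (%s) does not match predictions (%s)",
              paste(dim(B_prior), collapse = ","), paste(d, collapse = ","))
  }
  Wc <- C + rep(as.vector(B_prior), each = d[1])
  S <- .weighted_caps_sum(Uhat, Wc)
  if (squash_output) {
    capsule_tensor(.squash_fwd(S)$out, squashed = TRUE)
  } else {
    capsule_tensor(S, squashed = FALSE)
  }
}

# backward of the (pre-squash) aggregation
.route_bwd <- function(dS, Uhat, Wc) {
  d <- dim(Uhat); B <- d[1]; nl <- d[2]; no <- d[3]; do_ <- d[4]
  dUhat <- array(0, d)
  dWc <- .caps_agreement(Uhat, dS)
  for (j in seq_len(no)) {
    Mj <- matrix(Wc[, , j], B, nl)
    dSj <- matrix(dS[, j, ], B, do_)
    for (e in seq_len(do_)) dUhat[, , j, e] <- Mj * dSj[, e]
  }
  list(dUhat = dUhat, dWc = dWc)
}

#' Self-correlation routing (single pass)
#'
#' The full non-iterative routing mechanism: predictions via the
#' transformation tensor, the scaled Gram (self-correlation) tensor, the
#' softmax coupling coefficients, and the prior-weighted aggregation —
#' one fixed computation graph with no iteration, differentiable
#' end-to-end.
#'
#' @param U a squashed `capsule_tensor` or `(B, n_l, d_l)` array.
#' @param weights list with `W` and `B` as from [routing_weights()].
#' @param corr_scale see [self_correlation()].
#' @param squash_output see [route_capsules()].
#' @return A `capsule_tensor` `(B, n_out, d_out)`.
#' @export
self_correlation_routing <- function(U, weights,
                                     corr_scale = c("dl", "sqrt_dl"),
                                     squash_output = TRUE) {
  corr_scale <- match.arg(corr_scale)
  Uv <- .caps_values(U)
  fw <- .selfcorr_route_fwd(Uv, weights, corr_scale, squash_output)
  capsule_tensor(fw$out, squashed = squash_output)
}

.selfcorr_route_fwd <- function(U, weights, corr_scale, squash_output) {
  dl <- dim(U)[3]
  Uhat <- predict_capsules(U, weights$W)
  A <- self_correlation(Uhat, dl, corr_scale)
  L <- apply(A, c(1L, 2L, 4L), sum)
  C <- .softmax3_fwd(L)
  Wc <- C + rep(as.vector(weights$B), each = dim(U)[1])
  S <- .weighted_caps_sum(Uhat, Wc)
  sq <- if (squash_output) .squash_fwd(S) else NULL
  list(out = if (squash_output) sq$out else S,
       cache = list(U = U, Uhat = Uhat, C = C, Wc = Wc, S = S,
                    sqcache = if (squash_output) sq$cache else NULL,
                    dl = dl, corr_scale = corr_scale,
                    squash_output = squash_output, weights = weights))
}

.selfcorr_route_bwd <- function(dOut, cache) {
  w <- cache$weights
  dS <- if (cache$squash_output) .squash_bwd(dOut, cache$sqcache) else dOut
  rb <- .route_bwd(dS, cache$Uhat, cache$Wc)
  dUhat <- rb$dUhat
  dC <- rb$dWc
  dB <- apply(rb$dWc, c(2L, 3L), sum)
  dL <- .softmax3_bwd(dC, cache$C)
  dA <- .logits_bwd_toA(dL, dim(cache$Uhat)[2])
  dUhat <- dUhat + .self_correlation_bwd(dA, cache$Uhat, cache$dl,
                                         cache$corr_scale)
  pb <- .predict_bwd(dUhat, cache$U, w$W)
  list(dU = pb$dU, dW = pb$dW, dB = dB)
}

#' Dynamic routing (iterative baseline)
#'
#' Classic routing-by-agreement: logits start at zero; each iteration
#' computes softmax couplings, the coupling-weighted prediction sum, a
#' squashed output, and updates the logits by the prediction-output dot
#' products. Used as the in-package ablation baseline; its cost grows
#' linearly with `iterations` while self-correlation routing is a single
#' fixed pass.
#'
#' @param U a squashed `capsule_tensor` or `(B, n_l, d_l)` array.
#' @param W transformation array `(n_l, n_out, d_l, d_out)`.
#' @param iterations routing iterations (>= 1, default 3).
#' @return A `capsule_tensor` `(B, n_out, d_out)` (squashed).
#' @export
dynamic_routing <- function(U, W, iterations = 3) {
  if (!.is_count(iterations)) .stop_cfg("`iterations` must be an integer >= 1")
  Uv <- .caps_values(U)
  Uhat <- predict_capsules(Uv, W)
  fw <- .dynamic_fwd(Uhat, iterations)
  capsule_tensor(fw$out, squashed = TRUE)
}

.dynamic_fwd <- function(Uhat, iterations) {
  d <- dim(Uhat); B <- d[1]; nl <- d[2]; no <- d[3]
  blog <- array(0, c(B, nl, no))
  iters <- vector("list", iterations)
  V <- NULL
  for (r in seq_len(iterations)) {
    C <- .softmax3_fwd(blog)
    S <- .weighted_caps_sum(Uhat, C)
    sq <- .squash_fwd(S)
    V <- sq$out
    iters[[r]] <- list(C = C, sqcache = sq$cache, V = V)
    blog <- blog + .caps_agreement(Uhat, V)    # agreement update, every iter
  }
  list(out = V, cache = list(iters = iters, Uhat = Uhat,
                             iterations = iterations))
}

.dynamic_bwd <- function(dV, cache) {
  Uhat <- cache$Uhat
  R <- cache$iterations
  dUhat <- array(0, dim(Uhat))
  db_next <- NULL
  dVr <- dV
  for (r in R:1) {
    it <- cache$iters[[r]]
    dS <- .squash_bwd(dVr, it$sqcache)
    dC <- .caps_agreement(Uhat, dS)
    rb <- .route_bwd(dS, Uhat, it$C)           # dUhat += C * dS
    dUhat <- dUhat + rb$dUhat
    dblog <- .softmax3_bwd(dC, it$C)
    if (!is.null(db_next)) dblog <- dblog + db_next
    if (r > 1) {
      # blog_r = blog_{r-1} + agreement(Uhat, V_{r-1})
      db_next <- dblog
      Vprev <- cache$iters[[r - 1]]$V
      dVr <- .weighted_caps_sum(Uhat, dblog)
      d <- dim(Uhat)
      for (j in seq_len(d[3])) {
        Mj <- matrix(dblog[, , j], d[1], d[2])
        Vj <- matrix(Vprev[, j, ], d[1], d[4])
        for (e in seq_len(d[4])) {
          dUhat[, , j, e] <- dUhat[, , j, e] + Mj * Vj[, e]
        }
      }
    }
  }
  dUhat
}

#' Class scores from output capsules
#'
#' The Euclidean norm of each output capsule is its class score (the
#' magnitude-as-probability reading); the predicted class is the argmax,
#' with ties broken toward the lower class index.
#'
#' @param S a `capsule_tensor` `(B, n_out, d_out)` (squashed).
#' @return List with `scores` `(B, n_out)` and integer `predicted`
#'   (0-based class per trial).
#' @export
class_scores <- function(S) {
  V <- .caps_values(S)
  scores <- .caps_norms(V)
  predicted <- max.col(scores, ties.method = "first") - 1L
  list(scores = scores, predicted = predicted)
}
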