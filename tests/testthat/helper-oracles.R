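# Independent nested-loop reference implementations of every routing
# stage, written as literal transcriptions of the defining equations.
# They share no code with the package's vectorized paths.

loop_predict <- function(U, W) {
  d <- dim(W)
  B <- dim(U)[1]
  Uhat <- array(0, c(B, d[1], d[2], d[4]))
  for (b in seq_len(B)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    for (e in seq_len(d[4])) {
      acc <- 0
      for (q in seq_len(d[3])) acc <- acc + U[b, i, q] * W[i, j, q, e]
      Uhat[b, i, j, e] <- acc
    }
  }
  Uhat
}

loop_selfcorr <- function(Uhat, dl) {
  d <- dim(Uhat)
  A <- array(0, c(d[1], d[2], d[2], d[3]))
  for (b in seq_len(d[1])) for (i in seq_len(d[2])) for (k in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      acc <- 0
      for (e in seq_len(d[4])) acc <- acc + Uhat[b, i, j, e] * Uhat[b, k, j, e]
      A[b, i, k, j] <- acc / dl
    }
  }
  A
}

loop_coupling <- function(A) {
  d <- dim(A)
  C <- array(0, c(d[1], d[2], d[4]))
  for (b in seq_len(d[1])) for (i in seq_len(d[2])) {
    logits <- numeric(d[4])
    for (j in seq_len(d[4])) logits[j] <- sum(A[b, i, , j])
    e <- exp(logits - max(logits))
    C[b, i, ] <- e / sum(e)
  }
  C
}

loop_route <- function(Uhat, C, Bp) {
  d <- dim(Uhat)
  S <- array(0, c(d[1], d[3], d[4]))
  for (b in seq_len(d[1])) for (j in seq_len(d[3])) for (e in seq_len(d[4])) {
    acc <- 0
    for (i in seq_len(d[2])) {
      acc <- acc + Uhat[b, i, j, e] * (C[b, i, j] + Bp[i, j])
    }
    S[b, j, e] <- acc
  }
  S
}

# scalar squash written from the formula, not via the package
loop_squash_vec <- function(v) {
  r <- sqrt(sum(v^2))
  if (r < 1e-8) return(v * (1 - r / 2))
  (1 - exp(-r)) * v / r
}

loop_dynamic <- function(U, W, iterations) {
  Uhat <- loop_predict(U, W)
  d <- dim(Uhat)
  B <- d[1]; nl <- d[2]; no <- d[3]; do_ <- d[4]
  V <- array(0, c(B, no, do_))
  for (b in seq_len(B)) {
    blog <- matrix(0, nl, no)
    for (r in seq_len(iterations)) {
      C <- matrix(0, nl, no)
      for (i in seq_len(nl)) {
        e <- exp(blog[i, ] - max(blog[i, ]))
        C[i, ] <- e / sum(e)
      }
      for (j in seq_len(no)) {
        s <- numeric(do_)
        for (i in seq_len(nl)) s <- s + C[i, j] * Uhat[b, i, j, ]
        V[b, j, ] <- loop_squash_vec(s)
      }
      for (i in seq_len(nl)) for (j in seq_len(no)) {
        blog[i, j] <- blog[i, j] + sum(Uhat[b, i, j, ] * V[b, j, ])
      }
    }
  }
  V
}

rand_caps <- function(B, n, d, seed) {
  set.seed(seed)
  array(stats::rnorm(B * n * d), c(B, n, d))
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(b)))
}
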