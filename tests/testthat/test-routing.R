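test_that("prediction transform matches identity, zero, and loop-oracle cases", {
  U <- rand_caps(2, 1, 3, seed = 1)
  W_id <- array(0, c(1, 1, 3, 3))
  W_id[1, 1, , ] <- diag(3)
  expect_equal(predict_capsules(U, W_id)[, 1, 1, ], U[, 1, ],
               tolerance = 1e-12)
  expect_equal(predict_capsules(U, array(0, c(1, 2, 3, 4))),
               array(0, c(2, 1, 2, 4)))
  U2 <- rand_caps(3, 2, 2, seed = 2)
  set.seed(3)
  W <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  expect_lt(rel_err(predict_capsules(U2, W), loop_predict(U2, W)), 1e-12)
  expect_error(predict_capsules(U2, array(0, c(2, 2, 3, 2))), "match W")
})

test_that("self-correlation tensor is symmetric, scaled, and matches the loop oracle", {
  expect_equal(self_correlation(array(0, c(2, 3, 2, 4)), 4),
               array(0, c(2, 3, 3, 2)))
  # single capsule: the scalar ||v||^2 / d_l
  v <- c(1, 2, 3)
  Uhat1 <- array(v, c(1, 1, 1, 3))
  expect_equal(as.vector(self_correlation(Uhat1, 3)), sum(v^2) / 3,
               tolerance = 1e-12)
  set.seed(5)
  Uhat <- array(rnorm(2 * 4 * 2 * 3), c(2, 4, 2, 3))
  A <- self_correlation(Uhat, 3)
  expect_equal(A, aperm(A, c(1, 3, 2, 4)), tolerance = 1e-12)  # symmetry
  expect_lt(rel_err(A, loop_selfcorr(Uhat, 3)), 1e-12)
  # sqrt scaling option
  expect_equal(self_correlation(Uhat, 4, "sqrt_dl"),
               self_correlation(Uhat, 4, "dl") * 2, tolerance = 1e-12)
})

test_that("coupling coefficients are a proper softmax over output capsules", {
  A0 <- array(0, c(2, 3, 3, 4))
  C0 <- coupling_coefficients(A0)
  expect_equal(C0, array(0.25, c(2, 3, 4)), tolerance = 1e-12)
  set.seed(6)
  A <- array(rnorm(2 * 3 * 3 * 2), c(2, 3, 3, 2))
  C <- coupling_coefficients(A)
  expect_lt(rel_err(C, loop_coupling(A)), 1e-10)
  expect_true(all(C > 0 & C < 1))
  expect_equal(apply(C, c(1, 2), sum), matrix(1, 2, 3), tolerance = 1e-12)
  # pushing one output capsule's logits up by 20 saturates its coupling
  Abig <- A
  Abig[, , , 1] <- Abig[, , , 1] + 20 / 3   # +20 on the summed logit
  Cbig <- coupling_coefficients(Abig)
  expect_true(all(Cbig[, , 1] > 0.999))
  # stabilization: huge logits do not overflow
  expect_true(all(is.finite(coupling_coefficients(A + 500))))
  expect_error(coupling_coefficients(A * NA), "finite")
})

test_that("aggregation matches its closed form and the loop oracle", {
  Uhat0 <- array(0, c(2, 3, 2, 4))
  C <- array(0.5, c(2, 3, 2))
  Bp <- matrix(0.2, 3, 2)
  out0 <- route_capsules(Uhat0, C, Bp)
  expect_equal(out0$values, array(0, c(2, 2, 4)))
  # n_l = 1: S = (c + b) * Uhat before squash
  set.seed(7)
  Uh1 <- array(rnorm(1 * 1 * 2 * 3), c(1, 1, 2, 3))
  C1 <- array(c(0.3, 0.7), c(1, 1, 2))
  B1 <- matrix(c(0.1, -0.2), 1, 2)
  S1 <- route_capsules(Uh1, C1, B1, squash_output = FALSE)
  for (j in 1:2) {
    expect_equal(S1$values[1, j, ], (C1[1, 1, j] + B1[1, j]) * Uh1[1, 1, j, ],
                 tolerance = 1e-12)
  }
  Uhat <- array(rnorm(2 * 3 * 2 * 4), c(2, 3, 2, 4))
  Cr <- coupling_coefficients(self_correlation(Uhat, 4))
  Bp2 <- matrix(rnorm(6) * 0.1, 3, 2)
  S <- route_capsules(Uhat, Cr, Bp2, squash_output = FALSE)
  expect_lt(rel_err(S$values, loop_route(Uhat, Cr, Bp2)), 1e-10)
  expect_false(S$squashed)
  expect_error(route_capsules(Uhat, Cr[, 1:2, ], Bp2), "coupling shape")
})

test_that("self-correlation routing composes the four stages exactly", {
  set.seed(9)
  U <- capsule_tensor(squash(rand_caps(3, 4, 3, seed = 9)), squashed = TRUE)
  w <- routing_weights(4, 2, 3, 5, seed = 2)
  w$B <- matrix(rnorm(8) * 0.1, 4, 2)
  out <- self_correlation_routing(U, w)
  Uhat <- predict_capsules(U, w$W)
  A <- self_correlation(Uhat, 3)
  C <- coupling_coefficients(A)
  manual <- route_capsules(Uhat, C, w$B)
  expect_equal(out$values, manual$values, tolerance = 1e-12)
  expect_true(out$squashed)
})

test_that("routing a batch equals routing items one at a time", {
  U <- squash(rand_caps(4, 3, 2, seed = 13))
  w <- routing_weights(3, 2, 2, 4, seed = 5)
  full <- self_correlation_routing(U, w)$values
  for (b in 1:4) {
    one <- self_correlation_routing(array(U[b, , ], c(1, 3, 2)), w)$values
    expect_equal(full[b, , ], one[1, , ], tolerance = 1e-12)
  }
  fulld <- dynamic_routing(U, w$W, 3)$values
  for (b in 1:4) {
    one <- dynamic_routing(array(U[b, , ], c(1, 3, 2)), w$W, 3)$values
    expect_equal(fulld[b, , ], one[1, , ], tolerance = 1e-12)
  }
})

test_that("routing is equivariant under permutation of input capsules", {
  U <- squash(rand_caps(2, 5, 3, seed = 17))
  w <- routing_weights(5, 2, 3, 4, seed = 6)
  w$B <- matrix(rnorm(10) * 0.2, 5, 2)
  perm <- c(3, 5, 1, 2, 4)
  Up <- U[, perm, , drop = FALSE]
  wp <- list(W = w$W[perm, , , , drop = FALSE], B = w$B[perm, , drop = FALSE])
  expect_equal(self_correlation_routing(U, w)$values,
               self_correlation_routing(Up, wp)$values, tolerance = 1e-10)
  expect_equal(dynamic_routing(U, w$W, 3)$values,
               dynamic_routing(Up, wp$W, 3)$values, tolerance = 1e-10)
})

test_that("dynamic routing matches the loop reference and its closed forms", {
  # 1 iteration from zero logits: uniform coupling
  U <- squash(rand_caps(2, 3, 2, seed = 19))
  w <- routing_weights(3, 2, 2, 4, seed = 7)
  Uhat <- predict_capsules(U, w$W)
  one_iter <- dynamic_routing(U, w$W, 1)$values
  for (b in 1:2) for (j in 1:2) {
    s <- colSums(matrix(Uhat[b, , j, ], 3, 4)) / 2   # c = 1/n_out
    expect_equal(one_iter[b, j, ], loop_squash_vec(s), tolerance = 1e-10)
  }
  # 3 iterations vs independent loop implementation (n_l=3, n_out=2, d=2)
  U2 <- squash(rand_caps(2, 3, 2, seed = 23))
  w2 <- routing_weights(3, 2, 2, 2, seed = 8)
  expect_lt(rel_err(dynamic_routing(U2, w2$W, 3)$values,
                    loop_dynamic(U2, w2$W, 3)), 1e-10)
  # identical predictions for one class, zero for the other
  v <- c(0.5, -0.3, 0.2)
  Uh <- array(0, c(1, 4, 2, 3))
  for (i in 1:4) Uh[1, i, 1, ] <- v
  W_forced <- array(0, c(4, 2, 3, 3))
  # build a U/W pair realizing Uh: U rows are v, W maps identically to class 1
  for (i in 1:4) W_forced[i, 1, , ] <- diag(3)
  Uv <- array(rep(v, each = 4), c(1, 4, 3))
  out <- dynamic_routing(Uv, W_forced, 1)$values
  expect_equal(out[1, 1, ], loop_squash_vec(4 * v / 2), tolerance = 1e-10)
  expect_equal(out[1, 2, ], c(0, 0, 0))
  expect_error(dynamic_routing(Uv, W_forced, 0), "iterations")
})

test_that("margin loss gradients flow through self-correlation routing", {
  set.seed(31)
  U <- squash(rand_caps(2, 3, 2, seed = 29))
  w <- routing_weights(3, 2, 2, 3, seed = 9)
  targets <- rbind(c(1, 0), c(0, 1))
  loss_of <- function(w) {
    V <- self_correlation_routing(U, w)$values
    norms <- apply(V, c(1, 2), function(x) sqrt(sum(x^2)))
    margin_loss(norms, targets)
  }
  h <- 1e-5
  grad <- array(0, dim(w$W))
  for (i in seq_along(w$W)) {
    wp <- w; wp$W[i] <- wp$W[i] + h
    wm <- w; wm$W[i] <- wm$W[i] - h
    grad[i] <- (loss_of(wp) - loss_of(wm)) / (2 * h)
  }
  expect_true(all(is.finite(grad)))
  expect_gt(max(abs(grad)), 1e-4)
})

test_that("class scores are capsule norms with lower-index tie-breaking", {
  V <- array(0, c(2, 2, 2))
  V[1, 1, ] <- c(0.9, 0); V[1, 2, ] <- c(0.1, 0)
  V[2, 1, ] <- c(0, 0.4); V[2, 2, ] <- c(0.4, 0)   # tie
  cs <- class_scores(capsule_tensor(V, squashed = TRUE))
  expect_equal(cs$scores[1, ], c(0.9, 0.1))
  expect_equal(cs$predicted, c(0L, 0L))
  set.seed(37)
  Vr <- squash(rand_caps(5, 2, 6, seed = 41) * 3)
  sc <- class_scores(capsule_tensor(Vr, squashed = TRUE))$scores
  expect_true(all(sc >= 0 & sc < 1))
})
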