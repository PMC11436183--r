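test_that("squash matches its closed form and conventions", {
  expect_identical(squash(c(0, 0, 0, 0)), c(0, 0, 0, 0))
  v <- c(0.6, 0.8)  # unit norm
  expect_equal(sqrt(sum(squash(v)^2)), 1 - exp(-1), tolerance = 1e-12)
  out <- squash(c(3, 4))
  expect_equal(out, (1 - exp(-5)) * c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(sqrt(sum(out^2)), 0.9932621, tolerance = 1e-6)
  expect_error(squash(c(1, NA)), "finite")
})

test_that("squash preserves direction and obeys the norm law", {
  set.seed(8)
  for (rep in 1:20) {
    d <- sample(2:8, 1)
    s <- rnorm(d) * 10^runif(1, -8, 3)  # tiny through adversarially large
    r <- sqrt(sum(s^2))
    out <- squash(s)
    rn <- sqrt(sum(out^2))
    expect_lte(rn, 1)
    expect_equal(rn, 1 - exp(-r), tolerance = 1e-9)
    if (r > 1e-6) {
      cosang <- sum(out * s) / (rn * r)
      expect_equal(cosang, 1, tolerance = 1e-9)
    }
  }
  # strictly increasing in the input norm
  norms <- sapply(c(0.1, 0.5, 1, 2, 5, 10), function(r) {
    sqrt(sum(squash(c(r, 0))^2))
  })
  expect_true(all(diff(norms) > 0))
})

test_that("squash handles matrices and batched arrays consistently", {
  set.seed(2)
  m <- matrix(rnorm(6), 3, 2)
  sm <- squash(m)
  for (i in 1:3) expect_equal(sm[i, ], squash(m[i, ]), tolerance = 1e-12)
  arr <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  sa <- squash(arr)
  for (b in 1:2) for (i in 1:3) {
    expect_equal(sa[b, i, ], squash(arr[b, i, ]), tolerance = 1e-12)
  }
})

test_that("the layer plan has five convolutions, two poolings, and the stated kernels", {
  for (T in c(3073L, 2049L)) {
    cfg <- model_config(n_samples = T)
    plan <- stcg_plan(cfg)
    expect_equal(sum(plan$type == "conv"), 5L)
    expect_equal(sum(plan$type == "pool"), 2L)
    expect_equal(plan$kernel[2], "(124, 1)")
    expect_equal(plan$kernel[4], "(1, 16)")
    expect_equal(plan$out_width[7], 1L)           # geometry closes
    expect_equal(plan$out_maps[7], cfg$n_caps * cfg$d_caps)
  }
})

test_that("the realized forward shape matches the symbolic plan at full geometry", {
  for (T in c(3073L, 2049L)) {
    cfg <- model_config(n_samples = T, seed = 2)
    stcg <- build_stcg(cfg)
    X <- array(rnorm(1 * 124 * T), c(1, 124, T))
    caps <- stcg_forward(stcg, X)
    expect_equal(dim(caps$values), c(1L, cfg$n_caps, cfg$d_caps))
    expect_true(caps$squashed)
  }
})

test_that("forward shapes match the plan for randomized valid configurations", {
  set.seed(14)
  for (rep in 1:5) {
    n_caps <- sample(2:4, 1); d_caps <- sample(2:4, 1)
    cfg <- model_config(n_channels = sample(4:10, 1),
                        n_samples = 64, F1 = sample(2:4, 1),
                        TI = 2 * sample(3:8, 1) + 1, D = sample(1:2, 1),
                        F2 = n_caps * d_caps, pool1 = 2, pool2 = 4,
                        n_caps = n_caps, d_caps = d_caps,
                        d_out = sample(3:6, 1), dw_kernel = sample(3:8, 1),
                        seed = rep)
    plan <- stcg_plan(cfg)
    B <- sample(1:3, 1)
    X <- array(rnorm(B * cfg$n_channels * cfg$n_samples),
               c(B, cfg$n_channels, cfg$n_samples))
    caps <- stcg_forward(build_stcg(cfg), X)
    expect_equal(dim(caps$values),
                 c(B, attr(plan, "capsules")[["n_caps"]],
                   attr(plan, "capsules")[["d_caps"]]))
  }
})

test_that("primary capsule norms are squashed into [0, 1) and forward is deterministic", {
  cfg <- tiny_cfg()
  stcg <- build_stcg(cfg)
  set.seed(4)
  X <- array(rnorm(4 * 8 * 32) * 5, c(4, 8, 32))
  a <- stcg_forward(stcg, X)
  b <- stcg_forward(stcg, X)
  expect_identical(a$values, b$values)
  norms <- apply(a$values, c(1, 2), function(v) sqrt(sum(v^2)))
  expect_true(all(norms >= 0 & norms < 1))
})

test_that("spatial depthwise parameters scale with channel count, temporal ones do not", {
  base <- tiny_cfg()
  wide <- tiny_cfg(n_channels = 16)
  pb <- build_stcg(base)$params
  pw <- build_stcg(wide)$params
  expect_equal(length(pw$conv2$W), 2 * length(pb$conv2$W))
  expect_equal(length(pw$conv1$W), length(pb$conv1$W))
})

test_that("inexact capsule reshapes and geometry mismatches are rejected", {
  expect_error(tiny_cfg(F2 = 7), "reshape is inexact")
  stcg <- build_stcg(tiny_cfg())
  expect_error(stcg_forward(stcg, array(0, c(2, 8, 33))),
               "does not match config")
})
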