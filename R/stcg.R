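#' Squash nonlinearity for capsule vectors
#'
#' Rescales each capsule vector `s` to
#' `(1 - exp(-||s||)) * s / ||s||`: the direction is preserved while the
#' norm is squashed to `1 - exp(-||s||)`, strictly increasing in `||s||`
#' and bounded by 1, so a capsule's magnitude can be read as a presence
#' probability. The zero vector maps to the zero vector (the continuous
#' extension of the 0/0 limit, guarded by an epsilon on the norm).
#'
#' @param s a numeric vector (one capsule), a matrix (capsules in rows),
#'   or a 3-D array `(batch, n_capsules, dims)`.
#' @return Squashed capsules with the same shape as `s`.
#' @examples
#' sqrt(sum(squash(c(3, 4))^2))   # 1 - exp(-5)
#' squash(c(0, 0, 0, 0))          # stays zero
#' @export
squash <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(!is.finite(s))) {
    stop("squash() requires finite numeric input", call. = FALSE)
  }
  if (is.null(dim(s))) {
    S <- array(s, c(1L, 1L, length(s)))
    return(as.vector(.squash_fwd(S)$out))
  }
  if (length(dim(s)) == 2L) {
    S <- array(s, c(1L, nrow(s), ncol(s)))
    out <- .squash_fwd(S)$out
    return(matrix(out, nrow(s), ncol(s)))
  }
  if (length(dim(s)) == 3L) return(.squash_fwd(s)$out)
  stop("squash() expects a vector, matrix, or 3-D array", call. = FALSE)
}

# forward over (B, n, d); cache holds what the backward pass needs
.caps_norms <- function(S) {
  d <- dim(S)
  matrix(sqrt(rowSums(matrix(S * S, d[1] * d[2], d[3]))), d[1], d[2])
}

.squash_fwd <- function(S) {
  r <- .caps_norms(S)
  g <- ifelse(r < 1e-8, 1 - r / 2, (1 - exp(-r)) / pmax(r, 1e-300))
  V <- S * as.vector(g)
  list(out = V, cache = list(S = S, r = r, g = g))
}

.squash_bwd <- function(dV, cache) {
  S <- cache$S; r <- cache$r; g <- cache$g
  d <- dim(S)
  gp <- ifelse(r < 1e-3,
               -0.5 + r / 3 - r^2 / 8,
               ((1 + r) * exp(-r) - 1) / pmax(r, 1e-300)^2)
  dot <- matrix(rowSums(matrix(dV * S, d[1] * d[2], d[3])), d[1], d[2])
  coef <- ifelse(r < 1e-12, 0, gp * dot / pmax(r, 1e-300))
  dV * as.vector(g) + S * as.vector(coef)
}

#' Architecture configuration for the capsule network
#'
#' Holds every architectural hyperparameter of the spatio-temporal
#' capsule-generation (STCG) front-end and the routed capsule layer. The
#' STCG block comprises five convolutional and two pooling layers: a
#' temporal convolution (kernel `(1, TI)`, `F1` filters, same padding), a
#' spatial depthwise convolution (kernel `(n_channels, 1)`, multiplier
#' `D`) collapsing the channel axis, average pooling of width `pool1`, a
#' depthwise separable convolution (depthwise kernel `(1, 16)` then `F2`
#' pointwise `(1, 1)` kernels), average pooling of width `pool2`, and a
#' depthwise feature-fusion convolution spanning the residual temporal
#' extent whose output is reshaped into `n_caps` capsules of `d_caps`
#' dimensions (so `F2` must equal `n_caps * d_caps`). Batch
#' normalization + ELU follow convolutions 1, 2 and the pointwise stage
#' when `batch_norm = TRUE`.
#'
#' @param n_channels EEG channels `C` (default 124).
#' @param n_samples epoch length `T` in samples (default 3073 = 3 s at
#'   1024 Hz).
#' @param F1 temporal filter count.
#' @param TI temporal kernel length in samples.
#' @param D depth multiplier of the spatial depthwise convolution.
#' @param F2 pointwise filter count; must equal `n_caps * d_caps`.
#' @param pool1,pool2 temporal average-pooling widths.
#' @param n_caps,d_caps primary capsule count and dimension.
#' @param n_out output (class) capsule count; 2 for the binary task.
#' @param d_out output capsule dimension.
#' @param dw_kernel depthwise kernel length of the separable stage.
#' @param batch_norm apply batch normalization + ELU after convolutions
#'   1, 2 and the pointwise stage.
#' @param corr_scale denominator of the self-correlation tensor:
#'   `"dl"` divides the Gram matrix by the capsule dimension (the
#'   printed form), `"sqrt_dl"` by its square root (the attention
#'   convention).
#' @param squash_output squash the routed class capsules so their norms
#'   lie in `[0, 1)` as the margin loss expects.
#' @param seed integer seed for parameter initialization.
#' @return A validated `model_config` list.
#' @export
model_config <- function(n_channels = 124, n_samples = 3073,
                         F1 = 16, TI = 65, D = 2, F2 = 64,
                         pool1 = 4, pool2 = 8,
                         n_caps = 8, d_caps = 8, n_out = 2, d_out = 16,
                         dw_kernel = 16, batch_norm = TRUE,
                         corr_scale = c("dl", "sqrt_dl"),
                         squash_output = TRUE, seed = 1) {
  corr_scale <- match.arg(corr_scale)
  for (nm in c("n_channels", "n_samples", "F1", "TI", "D", "F2", "pool1",
               "pool2", "n_caps", "d_caps", "n_out", "d_out", "dw_kernel")) {
    if (!.is_count(get(nm))) .stop_cfg("`%s` must be a positive integer", nm)
  }
  cfg <- list(n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples),
              F1 = as.integer(F1), TI = as.integer(TI), D = as.integer(D),
              F2 = as.integer(F2), pool1 = as.integer(pool1),
              pool2 = as.integer(pool2), n_caps = as.integer(n_caps),
              d_caps = as.integer(d_caps), n_out = as.integer(n_out),
              d_out = as.integer(d_out), dw_kernel = as.integer(dw_kernel),
              batch_norm = isTRUE(batch_norm), corr_scale = corr_scale,
              squash_output = isTRUE(squash_output), seed = seed)
  class(cfg) <- "model_config"
  t1 <- cfg$n_samples %/% cfg$pool1
  t2 <- t1 %/% cfg$pool2
  if (t1 < 1L || t2 < 1L) {
    .stop_cfg("pooling (%d, %d) exhausts the %d temporal samples",
              cfg$pool1, cfg$pool2, cfg$n_samples)
  }
  if (cfg$F2 != cfg$n_caps * cfg$d_caps) {
    .stop_cfg(paste0("capsule reshape is inexact: F2 (%d) x 1 fused sample ",
                     "!= n_caps (%d) x d_caps (%d) = %d"),
              cfg$F2, cfg$n_caps, cfg$d_caps, cfg$n_caps * cfg$d_caps)
  }
  cfg
}

#' Reduced CPU-scale preset
#'
#' A small named configuration used throughout the test harness: 8
#' channels, 128 samples (1 s at 127 Hz), 8 temporal filters, 4 capsules
#' of dimension 4 with 8-dimensional class capsules. The skeleton (five
#' convolutions, two poolings, routing) is identical to the full-geometry
#' default; only the sizes shrink.
#'
#' @param ... overrides forwarded to [model_config()].
#' @return A `model_config`.
#' @export
reduced_config <- function(...) {
  defaults <- list(n_channels = 8, n_samples = 128, F1 = 8, TI = 33, D = 2,
                   F2 = 16, pool1 = 4, pool2 = 8, n_caps = 4, d_caps = 4,
                   n_out = 2, d_out = 8)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

#' Symbolic layer shape plan of the STCG block
#'
#' Returns one row per layer (five convolutional, two pooling) with its
#' kernel and predicted output shape, plus the final capsule shape. The
#' realized forward pass is tested against this plan.
#'
#' @param cfg a [model_config()].
#' @return A data.frame with columns `layer`, `name`, `type`,
#'   `kernel`, `out_maps`, `out_height`, `out_width`.
#' @export
stcg_plan <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  C <- cfg$n_channels; T <- cfg$n_samples
  M <- cfg$F1 * cfg$D
  t1 <- T %/% cfg$pool1
  t2 <- t1 %/% cfg$pool2
  plan <- data.frame(
    layer = 1:7,
    name = c("temporal_conv", "spatial_depthwise_conv", "avg_pool_1",
             "separable_depthwise_conv", "separable_pointwise_conv",
             "avg_pool_2", "fusion_depthwise_conv"),
    type = c("conv", "conv", "pool", "conv", "conv", "pool", "conv"),
    kernel = c(sprintf("(1, %d)", cfg$TI), sprintf("(%d, 1)", C),
               sprintf("(1, %d)", cfg$pool1), sprintf("(1, %d)", cfg$dw_kernel),
               "(1, 1)", sprintf("(1, %d)", cfg$pool2), sprintf("(1, %d)", t2)),
    out_maps = c(cfg$F1, M, M, M, cfg$F2, cfg$F2, cfg$F2),
    out_height = c(C, 1L, 1L, 1L, 1L, 1L, 1L),
    out_width = c(T, T, t1, t1, t1, t2, 1L),
    stringsAsFactors = FALSE
  )
  attr(plan, "capsules") <- c(n_caps = cfg$n_caps, d_caps = cfg$d_caps)
  plan
}

# Seeded parameter initialization for the STCG block. Conv weights use
# fan-in-scaled normals; biases start at zero, batch-norm at identity.
.stcg_init <- function(cfg) {
  M <- cfg$F1 * cfg$D
  t2 <- (cfg$n_samples %/% cfg$pool1) %/% cfg$pool2
  params <- list(
    conv1 = list(W = matrix(stats::rnorm(cfg$F1 * cfg$TI), cfg$F1, cfg$TI) *
                   sqrt(2 / cfg$TI),
                 b = numeric(cfg$F1)),
    conv2 = list(W = array(stats::rnorm(cfg$F1 * cfg$D * cfg$n_channels),
                           c(cfg$F1, cfg$D, cfg$n_channels)) *
                   sqrt(2 / cfg$n_channels),
                 b = numeric(M)),
    conv4d = list(W = matrix(stats::rnorm(M * cfg$dw_kernel), M, cfg$dw_kernel) *
                    sqrt(2 / cfg$dw_kernel),
                  b = numeric(M)),
    conv4p = list(W = matrix(stats::rnorm(cfg$F2 * M), cfg$F2, M) * sqrt(2 / M),
                  b = numeric(cfg$F2)),
    conv6 = list(W = matrix(stats::rnorm(cfg$F2 * t2), cfg$F2, t2) *
                   sqrt(2 / t2),
                 b = numeric(cfg$F2))
  )
  if (cfg$batch_norm) {
    params$bn1 <- list(gamma = rep(1, cfg$F1), beta = numeric(cfg$F1))
    params$bn2 <- list(gamma = rep(1, M), beta = numeric(M))
    params$bn4 <- list(gamma = rep(1, cfg$F2), beta = numeric(cfg$F2))
  }
  state <- if (cfg$batch_norm) {
    list(bn1 = list(mean = numeric(cfg$F1), var = rep(1, cfg$F1)),
         bn2 = list(mean = numeric(M), var = rep(1, M)),
         bn4 = list(mean = numeric(cfg$F2), var = rep(1, cfg$F2)))
  } else list()
  list(params = params, state = state)
}

#' Build the STCG parameter bundle and layer plan
#'
#' Initializes all trainable parameters of the spatio-temporal
#' capsule-generation block (seeded via `cfg$seed`) together with its
#' symbolic shape plan.
#'
#' @param cfg a [model_config()].
#' @return List with `params` (nested parameter arrays), `state`
#'   (batch-norm running statistics), `plan` (see [stcg_plan()]), and
#'   the `cfg` echo.
#' @export
build_stcg <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  init <- .with_seed(cfg$seed, .stcg_init(cfg))
  list(params = init$params, state = init$state, plan = stcg_plan(cfg),
       cfg = cfg)
}

# Internal forward with full caches (for backprop). X: (B, C, T).
# Returns capsules (B, n_caps, d_caps), squashed, plus caches and
# (in train mode) updated batch-norm running stats.
.stcg_fwd <- function(params, state, X, cfg, train = FALSE) {
  d <- dim(X)
  if (length(d) != 3L || d[2] != cfg$n_channels || d[3] != cfg$n_samples) {
    .stop_cfg("input geometry (%s) does not match config (channels=%d, samples=%d)",
              paste(d, collapse = ", "), cfg$n_channels, cfg$n_samples)
  }
  caches <- list()
  l1 <- .conv_time_fwd(X, params$conv1$W, params$conv1$b)
  caches$conv1 <- l1$cache
  h <- l1$out
  if (cfg$batch_norm) {
    bn <- .bn_fwd(h, params$bn1$gamma, params$bn1$beta,
                  state$bn1$mean, state$bn1$var, train)
    caches$bn1 <- bn$cache
    state$bn1 <- list(mean = bn$run_mean, var = bn$run_var)
    e <- .elu_fwd(bn$out); caches$elu1 <- e$cache; h <- e$out
  }
  l2 <- .conv_space_fwd(h, params$conv2$W, params$conv2$b)
  caches$conv2 <- l2$cache
  h <- l2$out
  if (cfg$batch_norm) {
    bn <- .bn_fwd(h, params$bn2$gamma, params$bn2$beta,
                  state$bn2$mean, state$bn2$var, train)
    caches$bn2 <- bn$cache
    state$bn2 <- list(mean = bn$run_mean, var = bn$run_var)
    e <- .elu_fwd(bn$out); caches$elu2 <- e$cache; h <- e$out
  }
  p1 <- .pool_fwd(h, cfg$pool1); caches$pool1 <- p1$cache
  l4d <- .conv_dw_time_fwd(p1$out, params$conv4d$W, params$conv4d$b)
  caches$conv4d <- l4d$cache
  l4p <- .conv_pw_fwd(l4d$out, params$conv4p$W, params$conv4p$b)
  caches$conv4p <- l4p$cache
  h <- l4p$out
  if (cfg$batch_norm) {
    bn <- .bn_fwd(h, params$bn4$gamma, params$bn4$beta,
                  state$bn4$mean, state$bn4$var, train)
    caches$bn4 <- bn$cache
    state$bn4 <- list(mean = bn$run_mean, var = bn$run_var)
    e <- .elu_fwd(bn$out); caches$elu4 <- e$cache; h <- e$out
  }
  p2 <- .pool_fwd(h, cfg$pool2); caches$pool2 <- p2$cache
  l6 <- .conv_fuse_fwd(p2$out, params$conv6$W, params$conv6$b)
  caches$conv6 <- l6$cache
  B <- d[1]
  # (B, F2) -> (B, n_caps, d_caps), capsule-major columns
  pre <- aperm(array(l6$out, c(B, cfg$d_caps, cfg$n_caps)), c(1L, 3L, 2L))
  sq <- .squash_fwd(pre)
  caches$squash <- sq$cache
  list(out = sq$out, caches = caches, state = state)
}

.stcg_bwd <- function(dCaps, caches, params, cfg) {
  B <- dim(dCaps)[1]
  dPre <- .squash_bwd(dCaps, caches$squash)
  dFuse <- matrix(aperm(dPre, c(1L, 3L, 2L)), B, cfg$F2)
  grads <- list()
  g6 <- .conv_fuse_bwd(dFuse, caches$conv6)
  grads$conv6 <- list(W = g6$dW, b = g6$db)
  dh <- .pool_bwd(g6$dX, caches$pool2)
  if (cfg$batch_norm) {
    dh <- .elu_bwd(dh, caches$elu4)
    gb <- .bn_bwd(dh, caches$bn4)
    grads$bn4 <- list(gamma = gb$dgamma, beta = gb$dbeta)
    dh <- gb$dX
  }
  g4p <- .conv_pw_bwd(dh, caches$conv4p)
  grads$conv4p <- list(W = g4p$dW, b = g4p$db)
  g4d <- .conv_dw_time_bwd(g4p$dX, caches$conv4d)
  grads$conv4d <- list(W = g4d$dW, b = g4d$db)
  dh <- .pool_bwd(g4d$dX, caches$pool1)
  if (cfg$batch_norm) {
    dh <- .elu_bwd(dh, caches$elu2)
    gb <- .bn_bwd(dh, caches$bn2)
    grads$bn2 <- list(gamma = gb$dgamma, beta = gb$dbeta)
    dh <- gb$dX
  }
  g2 <- .conv_space_bwd(dh, caches$conv2)
  grads$conv2 <- list(W = g2$dW, b = g2$db)
  dh <- g2$dX
  if (cfg$batch_norm) {
    dh <- .elu_bwd(dh, caches$elu1)
    gb <- .bn_bwd(dh, caches$bn1)
    grads$bn1 <- list(gamma = gb$dgamma, beta = gb$dbeta)
    dh <- gb$dX
  }
  g1 <- .conv_time_bwd(dh, caches$conv1)
  grads$conv1 <- list(W = g1$dW, b = g1$db)
  # reorder to match the params skeleton
  out <- list(conv1 = grads$conv1, conv2 = grads$conv2,
              conv4d = grads$conv4d, conv4p = grads$conv4p,
              conv6 = grads$conv6)
  if (cfg$batch_norm) {
    out$bn1 <- grads$bn1; out$bn2 <- grads$bn2; out$bn4 <- grads$bn4
  }
  list(grads = out, dX = g1$dX)
}

#' Run the STCG block forward
#'
#' Maps a batch of raw epochs to squashed primary capsules. Deterministic
#' given parameters and mode; in eval mode (`train = FALSE`) batch
#' normalization uses the stored running statistics.
#'
#' @param stcg a bundle from [build_stcg()].
#' @param X numeric array `(batch, channels, samples)` matching the
#'   configured geometry (a single epoch `(channels, samples)` matrix is
#'   promoted to a batch of one).
#' @param train use batch statistics (`TRUE`) or running statistics.
#' @return A `capsule_tensor`: list with `values`
#'   `(batch, n_caps, d_caps)` and `squashed = TRUE`.
#' @export
stcg_forward <- function(stcg, X, train = FALSE) {
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  fw <- .stcg_fwd(stcg$params, stcg$state, X, stcg$cfg, train = train)
  capsule_tensor(fw$out, squashed = TRUE)
}

#' Capsule tensor container
#'
#' A batch of capsule sets: `values` is `(batch, n_capsules, dims)`;
#' `squashed` records whether every capsule norm is already in `[0, 1)`.
#'
#' @param values numeric 3-D array `(batch, n_capsules, dims)`.
#' @param squashed logical flag.
#' @return A `capsule_tensor` list.
#' @export
capsule_tensor <- function(values, squashed = FALSE) {
  if (length(dim(values)) != 3L) {
    .stop_cfg("capsule values must be (batch, n_capsules, dims)")
  }
  structure(list(values = values, squashed = isTRUE(squashed)),
            class = "capsule_tensor")
}

#' @export
print.capsule_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<capsule_tensor> batch %d, %d capsules x %d dims (%s)\n",
              d[1], d[2], d[3],
              if (x$squashed) "squashed" else "unsquashed"))
  invisible(x)
}

# coerce capsule_tensor or bare array to a (B, n, d) array
.caps_values <- function(U) {
  if (inherits(U, "capsule_tensor")) U$values else U
}
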