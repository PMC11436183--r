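# Full capsule-network assembly: front-end (STCG or traditional
# square-kernel) -> routing (self-correlation or dynamic) -> class-capsule
# norms -> margin loss, with the complete hand-written backward chain.

#' Initialize a capsule-network model
#'
#' Builds the parameter bundle for one of the four architecture variants
#' used by the ablation grid: the spatio-temporal (STCG) or traditional
#' (two square-kernel convolutions, matched capsule geometry) front-end,
#' routed by the self-correlation mechanism or by iterative dynamic
#' routing. Initialization is seeded by `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @param frontend `"stcg"` or `"traditional"`.
#' @param routing `"selfcorr"` or `"dynamic"`.
#' @param iterations dynamic-routing iterations (ignored for selfcorr).
#' @return A `stcaps_model` list with `params`, `state`, `cfg`, and the
#'   variant tags.
#' @export
init_model <- function(cfg, frontend = c("stcg", "traditional"),
                       routing = c("selfcorr", "dynamic"), iterations = 3) {
  frontend <- match.arg(frontend)
  routing <- match.arg(routing)
  if (!.is_count(iterations)) .stop_cfg("`iterations` must be an integer >= 1")
  if (frontend == "stcg") {
    built <- build_stcg(cfg)
    front <- built$params
    state <- built$state
  } else {
    front <- .with_seed(cfg$seed, .traditional_init(cfg))
    state <- list()
  }
  rw <- routing_weights(cfg$n_caps, cfg$n_out, cfg$d_caps, cfg$d_out,
                        seed = cfg$seed + 1)
  if (routing == "dynamic") rw$B <- NULL  # classic algorithm has no priors
  structure(list(params = list(front = front, routing = rw),
                 state = state, cfg = cfg, frontend = frontend,
                 routing = routing, iterations = as.integer(iterations)),
            class = "stcaps_model")
}

#' @export
print.stcaps_model <- function(x, ...) {
  cat(sprintf("<stcaps_model> %s front-end + %s routing; %d caps x %d dims -> %d x %d\n",
              x$frontend, x$routing, x$cfg$n_caps, x$cfg$d_caps,
              x$cfg$n_out, x$cfg$d_out))
  invisible(x)
}

# traditional front-end: two square-kernel convolutions (stride 2) + ELU,
# global average pooling, capsule reshape. Matched capsule geometry:
# conv2 emits n_caps * d_caps maps.
.traditional_init <- function(cfg, k = 3L) {
  F1 <- cfg$F1; F2 <- cfg$n_caps * cfg$d_caps
  h1 <- (cfg$n_channels - k) %/% 2L + 1L
  w1 <- (cfg$n_samples - k) %/% 2L + 1L
  if (h1 < k || w1 < k) {
    .stop_cfg("traditional front-end: %dx%d kernel does not fit twice in (%d, %d)",
              k, k, cfg$n_channels, cfg$n_samples)
  }
  list(convA = list(W = array(stats::rnorm(F1 * 1 * k * k), c(F1, 1L, k, k)) *
                      sqrt(2 / (k * k)),
                    b = numeric(F1)),
       convB = list(W = array(stats::rnorm(F2 * F1 * k * k), c(F2, F1, k, k)) *
                      sqrt(2 / (F1 * k * k)),
                    b = numeric(F2)))
}

.traditional_fwd <- function(front, X, cfg) {
  B <- dim(X)[1]
  X4 <- array(X, c(B, 1L, dim(X)[2], dim(X)[3]))
  a <- .conv2d_fwd(X4, front$convA$W, front$convA$b, c(2L, 2L))
  ea <- .elu_fwd(a$out)
  b2 <- .conv2d_fwd(ea$out, front$convB$W, front$convB$b, c(2L, 2L))
  eb <- .elu_fwd(b2$out)
  g <- .gap_fwd(eb$out)
  pre <- aperm(array(g$out, c(B, cfg$d_caps, cfg$n_caps)), c(1L, 3L, 2L))
  sq <- .squash_fwd(pre)
  list(out = sq$out,
       caches = list(convA = a$cache, eluA = ea$cache, convB = b2$cache,
                     eluB = eb$cache, gap = g$cache, squash = sq$cache))
}

.traditional_bwd <- function(dCaps, caches, cfg) {
  B <- dim(dCaps)[1]
  dPre <- .squash_bwd(dCaps, caches$squash)
  dGap <- matrix(aperm(dPre, c(1L, 3L, 2L)), B, cfg$n_caps * cfg$d_caps)
  dh <- .gap_bwd(dGap, caches$gap)
  dh <- .elu_bwd(dh, caches$eluB)
  gB <- .conv2d_bwd(dh, caches$convB)
  dh <- .elu_bwd(gB$dX, caches$eluA)
  gA <- .conv2d_bwd(dh, caches$convA)
  list(grads = list(convA = list(W = gA$dW, b = gA$db),
                    convB = list(W = gB$dW, b = gB$db)),
       dX = NULL)
}

# One full forward pass. Returns class-capsule values V (B, n_out, d_out),
# norms, and all caches needed for .model_bwd. Train mode also returns
# updated batch-norm state.
.model_fwd <- function(model, X, train = FALSE) {
  cfg <- model$cfg
  if (model$frontend == "stcg") {
    fw <- .stcg_fwd(model$params$front, model$state, X, cfg, train = train)
    U <- fw$out
    front_caches <- fw$caches
    state <- fw$state
  } else {
    fw <- .traditional_fwd(model$params$front, X, cfg)
    U <- fw$out
    front_caches <- fw$caches
    state <- model$state
  }
  if (model$routing == "selfcorr") {
    rt <- .selfcorr_route_fwd(U, model$params$routing, cfg$corr_scale,
                              cfg$squash_output)
    V <- rt$out
    route_cache <- rt$cache
  } else {
    Uhat <- predict_capsules(U, model$params$routing$W)
    rt <- .dynamic_fwd(Uhat, model$iterations)
    V <- rt$out
    route_cache <- c(rt$cache, list(U = U))
  }
  norms <- .caps_norms(V)
  list(V = V, norms = norms, U = U,
       caches = list(front = front_caches, route = route_cache),
       state = state)
}

# Backward from the margin loss. Returns grads in the params skeleton.
.model_bwd <- function(model, fwd, targets, margin = margin_params()) {
  cfg <- model$cfg
  dnorm <- .margin_loss_grad(fwd$norms, targets, margin)
  r <- pmax(fwd$norms, 1e-12)
  dV <- fwd$V * as.vector(dnorm / r)
  if (model$routing == "selfcorr") {
    rb <- .selfcorr_route_bwd(dV, fwd$caches$route)
    dU <- rb$dU
    g_routing <- list(W = rb$dW, B = rb$dB)
  } else {
    dUhat <- .dynamic_bwd(dV, fwd$caches$route)
    pb <- .predict_bwd(dUhat, fwd$caches$route$U, model$params$routing$W)
    dU <- pb$dU
    g_routing <- list(W = pb$dW)
  }
  if (model$frontend == "stcg") {
    fb <- .stcg_bwd(dU, fwd$caches$front, model$params$front, cfg)
    g_front <- fb$grads
  } else {
    fb <- .traditional_bwd(dU, fwd$caches$front, cfg)
    g_front <- fb$grads
  }
  list(front = g_front, routing = g_routing)
}

# loss + grads for one batch (used by the trainer and by gradient checks)
.model_loss <- function(model, X, targets, margin = margin_params(),
                        train = TRUE, want_grads = TRUE) {
  fwd <- .model_fwd(model, X, train = train)
  loss <- margin_loss(fwd$norms, targets, margin)
  out <- list(loss = loss, norms = fwd$norms, state = fwd$state)
  if (want_grads) out$grads <- .model_bwd(model, fwd, targets, margin)
  out
}
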