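# Internal helpers: scoped RNG, nested parameter-list arithmetic, Adam.

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Apply f elementwise over parallel nested lists of arrays, preserving
# structure. All arguments must share the exact same list skeleton.
.param_map <- function(f, ...) {
  args <- list(...)
  first <- args[[1L]]
  if (is.list(first)) {
    out <- lapply(seq_along(first), function(i) {
      do.call(.param_map, c(list(f), lapply(args, `[[`, i)))
    })
    names(out) <- names(first)
    out
  } else {
    do.call(f, args)
  }
}

.param_zeros_like <- function(p) .param_map(function(x) x * 0, p)

.param_add <- function(a, b) .param_map(`+`, a, b)

# Flatten a nested parameter list into one numeric vector (dims dropped),
# and write a vector back into the skeleton. Used by gradient checks.
.param_unlist <- function(p) unlist(p, use.names = FALSE)

.param_relist <- function(vec, skeleton) {
  pos <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  rec(skeleton)
}

# Adam optimizer over nested parameter lists.
.adam_init <- function(params) {
  list(t = 0L, m = .param_zeros_like(params), v = .param_zeros_like(params))
}

.adam_step <- function(state, params, grads, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .param_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .param_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(state = state, params = params)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

.stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
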