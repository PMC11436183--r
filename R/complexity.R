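#' Analytic parameter and FLOP accounting
#'
#' Closed-form per-layer multiply-accumulate (MAC) and trainable-parameter
#' counts for one input epoch, for any front-end/routing combination.
#' Convention: 1 MAC = 2 FLOPs; element-wise extras (activation,
#' normalization scale/shift, softmax exponentials and divisions, pooling
#' additions, squash) are counted at one FLOP per scalar operation. The
#' counts are exact consequences of the configured shapes, not profiler
#' measurements; the test suite validates them against independent
#' per-layer hand counts.
#'
#' Routing-only costs scale differently with the capsule count `n_l`:
#' self-correlation routing pays O(n_l^2 * n_out * d_out) for its Gram
#' tensor in a single pass, while dynamic routing pays
#' O(iterations * n_l * n_out * d_out); which mechanism is cheaper
#' therefore depends on the geometry (see the methods vignette).
#'
#' @param cfg a [model_config()].
#' @param routing `"selfcorr"` or `"dynamic"`.
#' @param frontend `"stcg"` or `"traditional"`.
#' @param iterations dynamic-routing iterations.
#' @return List with `layers` (data.frame: `name`, `params`, `macs`,
#'   `extra_flops`, `flops`), `total_params`, `total_macs`,
#'   `total_flops`, and `routing_flops` (the routing stages alone,
#'   excluding the shared prediction transform).
#' @export
count_complexity <- function(cfg, routing = c("selfcorr", "dynamic"),
                             frontend = c("stcg", "traditional"),
                             iterations = 3) {
  routing <- match.arg(routing)
  frontend <- match.arg(frontend)
  C <- cfg$n_channels; T <- cfg$n_samples
  F1 <- cfg$F1; D <- cfg$D; M <- F1 * D; F2 <- cfg$F2; K <- cfg$dw_kernel
  t1 <- T %/% cfg$pool1; t2 <- t1 %/% cfg$pool2
  nl <- cfg$n_caps; dl <- cfg$d_caps; no <- cfg$n_out; do_ <- cfg$d_out
  rows <- list()
  add <- function(name, params, macs, extra = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, params = params, macs = macs, extra_flops = extra,
      flops = 2 * macs + extra, stringsAsFactors = FALSE)
  }
  if (frontend == "stcg") {
    add("temporal_conv", F1 * cfg$TI + F1, F1 * C * T * cfg$TI)
    if (cfg$batch_norm) add("bn_elu_1", 2 * F1, 0, 3 * F1 * C * T)
    add("spatial_depthwise_conv", F1 * D * C + M, M * T * C)
    if (cfg$batch_norm) add("bn_elu_2", 2 * M, 0, 3 * M * T)
    add("avg_pool_1", 0, 0, M * T)
    add("separable_depthwise_conv", M * K + M, M * t1 * K)
    add("separable_pointwise_conv", F2 * M + F2, F2 * M * t1)
    if (cfg$batch_norm) add("bn_elu_4", 2 * F2, 0, 3 * F2 * t1)
    add("avg_pool_2", 0, 0, F2 * t1)
    add("fusion_depthwise_conv", F2 * t2 + F2, F2 * t2)
    add("primary_squash", 0, nl * dl, nl * dl + 3 * nl)
  } else {
    k <- 3L
    h1 <- (C - k) %/% 2L + 1L; w1 <- (T - k) %/% 2L + 1L
    h2 <- (h1 - k) %/% 2L + 1L; w2 <- (w1 - k) %/% 2L + 1L
    add("square_conv_1", F1 * k * k + F1, F1 * h1 * w1 * k * k,
        F1 * h1 * w1)
    add("square_conv_2", F2 * F1 * k * k + F2, F2 * h2 * w2 * F1 * k * k,
        F2 * h2 * w2)
    add("global_avg_pool", 0, 0, F2 * h2 * w2)
    add("primary_squash", 0, nl * dl, nl * dl + 3 * nl)
  }
  add("prediction_transform",
      nl * no * dl * do_ + if (routing == "selfcorr") nl * no else 0,
      nl * no * dl * do_)
  if (routing == "selfcorr") {
    add("self_correlation_tensor", 0, nl * nl * no * do_, nl * nl * no)
    add("coupling_softmax", 0, 0, nl * nl * no + 3 * nl * no)
    add("prior_weighted_aggregation", 0, nl * no * do_, nl * no)
    add("output_squash", 0, no * do_, no * do_ + 3 * no)
    routing_stages <- c("self_correlation_tensor", "coupling_softmax",
                        "prior_weighted_aggregation", "output_squash")
  } else {
    add(sprintf("dynamic_routing_%d_iterations", iterations), 0,
        iterations * (2 * nl * no * do_ + no * do_),
        iterations * (3 * nl * no + no * do_ + 3 * no))
    routing_stages <- sprintf("dynamic_routing_%d_iterations", iterations)
  }
  layers <- do.call(rbind, rows)
  list(layers = layers,
       total_params = sum(layers$params),
       total_macs = sum(layers$macs),
       total_flops = sum(layers$flops),
       routing_flops = sum(layers$flops[layers$name %in% routing_stages]))
}
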