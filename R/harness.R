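# Ablation grid and parameter-sensitivity sweeps.

.variant_grid <- data.frame(
  frontend = c("traditional", "traditional", "stcg", "stcg"),
  routing = c("dynamic", "selfcorr", "dynamic", "selfcorr"),
  stringsAsFactors = FALSE
)

#' Ablation over front-end and routing variants
#'
#' Trains and evaluates each requested architecture variant —
#' {traditional, spatio-temporal capsules} x {dynamic, self-correlation
#' routing} — under identical conditions: the same seeded stratified
#' hold-out split, the same initialization and shuffling seeds, and the
#' same training budget, so rows differ only in architecture.
#'
#' @inheritParams train_model
#' @param eset an [eeg_epoch_set()].
#' @param variants character vector of `"frontend:routing"` tags drawn
#'   from `traditional:dynamic`, `traditional:selfcorr`, `stcg:dynamic`,
#'   `stcg:selfcorr`; default all four (the classic 4-row grid).
#' @param test_frac held-out fraction per class.
#' @return A data.frame with one row per variant: `frontend`, `routing`,
#'   `train_accuracy`, `test_accuracy`.
#' @export
ablation_run <- function(eset, variants = NULL, cfg, tcfg = train_config(),
                         iterations = 3, margin = margin_params(),
                         test_frac = 0.2) {
  validate_epoch_set(eset)
  grid <- .variant_grid
  grid$tag <- paste(grid$frontend, grid$routing, sep = ":")
  if (!is.null(variants)) {
    bad <- setdiff(variants, grid$tag)
    if (length(bad) > 0) {
      .stop_cfg("unknown variant(s): %s (valid: %s)",
                paste(bad, collapse = ", "), paste(grid$tag, collapse = ", "))
    }
    grid <- grid[match(variants, grid$tag), , drop = FALSE]
  }
  split <- stratified_holdout(eset$labels, test_frac, seed = tcfg$seed)
  tr <- eeg_epoch_set(eset$data[split$train, , , drop = FALSE],
                      eset$labels[split$train], eset$sfreq, eset$modality)
  te <- eeg_epoch_set(eset$data[split$test, , , drop = FALSE],
                      eset$labels[split$test], eset$sfreq, eset$modality)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- train_model(tr, cfg, tcfg, grid$frontend[i], grid$routing[i],
                       iterations, margin)
    ev <- evaluate_model(fit, te)
    h <- fit$report$history
    data.frame(frontend = grid$frontend[i], routing = grid$routing[i],
               train_accuracy = if (nrow(h) > 0) h$accuracy[nrow(h)] else NA,
               test_accuracy = ev$accuracy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sensitivity sweep over capsule count or dimension
#'
#' Re-trains the model along one architectural axis — the primary capsule
#' count (`n_caps`, canonical range 2..12) or the capsule dimension
#' (`d_caps`, canonical range 1..8) — keeping the capsule reshape exact
#' by re-deriving `F2 = n_caps * d_caps` at every point. Each point
#' reports hold-out accuracy and the total trainable parameter count.
#' Sweep points whose configuration is infeasible are recorded as skipped
#' with the reason instead of aborting the sweep.
#'
#' @inheritParams ablation_run
#' @param axis `"n_caps"` or `"d_caps"`.
#' @param values integer settings to sweep; defaults to 2:12 for
#'   `n_caps` and 1:8 for `d_caps`.
#' @param frontend,routing architecture variant (see [init_model()]).
#' @return A data.frame with columns `axis`, `value`, `accuracy`,
#'   `n_params`, `skipped`, `reason`.
#' @export
sensitivity_sweep <- function(eset, axis = c("n_caps", "d_caps"),
                              values = NULL, cfg, tcfg = train_config(),
                              frontend = "stcg", routing = "selfcorr",
                              iterations = 3, margin = margin_params(),
                              test_frac = 0.2) {
  axis <- match.arg(axis)
  validate_epoch_set(eset)
  if (is.null(values)) values <- if (axis == "n_caps") 2:12 else 1:8
  split <- stratified_holdout(eset$labels, test_frac, seed = tcfg$seed)
  tr <- eeg_epoch_set(eset$data[split$train, , , drop = FALSE],
                      eset$labels[split$train], eset$sfreq, eset$modality)
  te <- eeg_epoch_set(eset$data[split$test, , , drop = FALSE],
                      eset$labels[split$test], eset$sfreq, eset$modality)
  rows <- lapply(values, function(v) {
    out <- data.frame(axis = axis, value = v, accuracy = NA_real_,
                      n_params = NA_real_, skipped = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    cfg_v <- tryCatch({
      args <- unclass(cfg)
      args[[axis]] <- v
      args$F2 <- if (axis == "n_caps") v * cfg$d_caps else cfg$n_caps * v
      do.call(model_config, args)
    }, error = function(e) e)
    if (inherits(cfg_v, "error")) {
      out$skipped <- TRUE
      out$reason <- conditionMessage(cfg_v)
      return(out)
    }
    out$n_params <- count_complexity(cfg_v, routing, frontend,
                                     iterations)$total_params
    fit <- train_model(tr, cfg_v, tcfg, frontend, routing, iterations,
                       margin)
    out$accuracy <- evaluate_model(fit, te)$accuracy
    out
  })
  do.call(rbind, rows)
}
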