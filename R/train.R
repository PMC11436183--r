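#' Optimization hyperparameters
#'
#' Defaults mirror the training protocol the architecture was designed
#' under: Adam with learning rate 0.02, batch size 20, 120 epochs, margin
#' loss. Reduced-epoch profiles are appropriate for CPU-scale synthetic
#' experiments.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size trials per optimization step (>= 1).
#' @param epochs passes over the training set (>= 0; 0 returns the
#'   freshly initialized model untouched).
#' @param seed integer seed controlling data order (model initialization
#'   is seeded separately by the model config).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.02, batch_size = 20,
                         epochs = 120, seed = 1) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    .stop_cfg("`learning_rate` must be > 0")
  }
  if (!.is_count(batch_size)) .stop_cfg("`batch_size` must be >= 1")
  if (!is.numeric(epochs) || epochs < 0 || epochs != round(epochs)) {
    .stop_cfg("`epochs` must be a non-negative integer")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = seed),
            class = "train_config")
}

.check_geometry <- function(eset, cfg) {
  d <- dim(eset$data)
  if (d[2] != cfg$n_channels || d[3] != cfg$n_samples) {
    .stop_cfg("epoch geometry (%d channels, %d samples) does not match config (%d, %d)",
              d[2], d[3], cfg$n_channels, cfg$n_samples)
  }
}

.one_hot <- function(labels, n_classes = 2L) {
  out <- matrix(0, length(labels), n_classes)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

#' Train a capsule network on an epoch set
#'
#' End-to-end optimization of the front-end and routing parameters
#' against the margin loss with Adam. Fully seeded: the model
#' initialization comes from `cfg$seed`, the per-epoch shuffling from
#' `tcfg$seed`, so the same (data, config, seeds) triple reproduces the
#' loss history exactly. `epochs = 0` returns the initialized, untrained
#' model.
#'
#' @param train an [eeg_epoch_set()] to fit on.
#' @param cfg a [model_config()] matching the epoch geometry.
#' @param tcfg a [train_config()].
#' @param frontend,routing,iterations architecture variant, see
#'   [init_model()].
#' @param margin a [margin_params()].
#' @param verbose print per-epoch progress to stderr.
#' @return A `stcaps_fit`: list with the trained `model` and a `report`
#'   (per-epoch `history` of train loss/accuracy, config echoes, seed,
#'   wall time in seconds).
#' @export
train_model <- function(train, cfg, tcfg = train_config(),
                        frontend = c("stcg", "traditional"),
                        routing = c("selfcorr", "dynamic"),
                        iterations = 3, margin = margin_params(),
                        verbose = FALSE) {
  frontend <- match.arg(frontend)
  routing <- match.arg(routing)
  validate_epoch_set(train)
  .check_geometry(train, cfg)
  if (n_trials(train) < 1) .stop_cfg("empty training set")
  t0 <- proc.time()[["elapsed"]]
  model <- init_model(cfg, frontend, routing, iterations)
  n <- n_trials(train)
  targets_all <- .one_hot(train$labels, cfg$n_out)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  if (tcfg$epochs > 0) {
    opt <- .adam_init(model$params)
    .with_seed(tcfg$seed, {
      for (ep in seq_len(tcfg$epochs)) {
        idx <- sample(n)
        starts <- seq(1L, n, by = tcfg$batch_size)
        ep_loss <- 0; ep_correct <- 0L
        for (s in starts) {
          batch <- idx[s:min(s + tcfg$batch_size - 1L, n)]
          X <- train$data[batch, , , drop = FALSE]
          tg <- targets_all[batch, , drop = FALSE]
          res <- .model_loss(model, X, tg, margin, train = TRUE)
          model$state <- res$state
          step <- .adam_step(opt, model$params, res$grads, tcfg$learning_rate)
          opt <- step$state
          model$params <- step$params
          ep_loss <- ep_loss + res$loss * length(batch)
          pred <- max.col(res$norms, ties.method = "first") - 1L
          ep_correct <- ep_correct + sum(pred == train$labels[batch])
        }
        history <- rbind(history,
                         data.frame(epoch = ep, loss = ep_loss / n,
                                    accuracy = ep_correct / n * 100))
        if (verbose) {
          message(sprintf("epoch %3d  loss %.4f  acc %5.1f%%",
                          ep, ep_loss / n, ep_correct / n * 100))
        }
      }
    })
  }
  report <- list(history = history, cfg = cfg, tcfg = tcfg,
                 frontend = frontend, routing = routing,
                 seed = tcfg$seed,
                 wall_time = proc.time()[["elapsed"]] - t0)
  structure(list(model = model, report = report), class = "stcaps_fit")
}

#' @export
print.stcaps_fit <- function(x, ...) {
  h <- x$report$history
  cat(sprintf("<stcaps_fit> %s + %s, %d epochs", x$report$frontend,
              x$report$routing, nrow(h)))
  if (nrow(h) > 0) {
    cat(sprintf("; final train loss %.4f, accuracy %.1f%%",
                h$loss[nrow(h)], h$accuracy[nrow(h)]))
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a fitted model on an epoch set
#'
#' Forward pass in eval mode (batch normalization uses running
#' statistics), argmax of the class-capsule norms, confusion counts and
#' accuracy with perception as the positive class. Deterministic.
#'
#' @param fit a `stcaps_fit` from [train_model()] (or a bare
#'   `stcaps_model`).
#' @param test an [eeg_epoch_set()].
#' @param batch_size evaluation batch size (memory control only).
#' @return List with `counts` ([confusion_counts()]), `accuracy`
#'   (percent), and the per-trial `predicted` classes.
#' @export
evaluate_model <- function(fit, test, batch_size = 50) {
  model <- if (inherits(fit, "stcaps_fit")) fit$model else fit
  validate_epoch_set(test)
  .check_geometry(test, model$cfg)
  n <- n_trials(test)
  predicted <- integer(n)
  for (s in seq(1L, n, by = batch_size)) {
    batch <- s:min(s + batch_size - 1L, n)
    fwd <- .model_fwd(model, test$data[batch, , , drop = FALSE],
                      train = FALSE)
    predicted[batch] <- max.col(fwd$norms, ties.method = "first") - 1L
  }
  counts <- confusion_counts(predicted, test$labels)
  list(counts = counts, accuracy = accuracy(counts), predicted = predicted)
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold on the fold's complement and evaluates on
#' the held-out fold; folds are stratified and seeded via
#' [make_cv_folds()]. All folds share the model-config seed; data order
#' within each fold training run is seeded deterministically from
#' `tcfg$seed` and the fold index.
#'
#' @inheritParams train_model
#' @param eset an [eeg_epoch_set()].
#' @param k number of folds.
#' @return List with per-fold `reports`, the `fold_plan`, per-fold
#'   `accuracies`, and their `mean`/`sd`.
#' @export
cross_validate <- function(eset, k, cfg, tcfg = train_config(),
                           frontend = c("stcg", "traditional"),
                           routing = c("selfcorr", "dynamic"),
                           iterations = 3, margin = margin_params()) {
  frontend <- match.arg(frontend)
  routing <- match.arg(routing)
  validate_epoch_set(eset)
  plan <- make_cv_folds(eset$labels, k, seed = tcfg$seed)
  accuracies <- numeric(k)
  reports <- vector("list", k)
  for (fold in seq_len(k)) {
    test_idx <- which(plan$assignments == fold)
    train_idx <- which(plan$assignments != fold)
    tr <- eeg_epoch_set(eset$data[train_idx, , , drop = FALSE],
                        eset$labels[train_idx], eset$sfreq, eset$modality)
    te <- eeg_epoch_set(eset$data[test_idx, , , drop = FALSE],
                        eset$labels[test_idx], eset$sfreq, eset$modality)
    fold_tcfg <- tcfg
    fold_tcfg$seed <- tcfg$seed + fold
    fit <- train_model(tr, cfg, fold_tcfg, frontend, routing, iterations,
                       margin)
    ev <- evaluate_model(fit, te)
    accuracies[fold] <- ev$accuracy
    reports[[fold]] <- c(fit$report, list(test_accuracy = ev$accuracy))
  }
  list(reports = reports, fold_plan = plan, accuracies = accuracies,
       mean = mean(accuracies), sd = stats::sd(accuracies))
}
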