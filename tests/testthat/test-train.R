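test_that("zero epochs returns the seeded initialization untouched", {
  eset <- tiny_eset()
  cfg <- tiny_cfg(n_channels = 8, n_samples = 128, pool1 = 4, pool2 = 4,
                  TI = 9)
  fit <- train_model(eset, cfg, train_config(epochs = 0, seed = 2))
  fresh <- init_model(cfg)
  expect_identical(fit$model$params, fresh$params)
  expect_equal(nrow(fit$report$history), 0L)
})

test_that("training is reproducible: same seeds, same loss history", {
  eset <- tiny_eset()
  cfg <- tiny_cfg(n_channels = 8, n_samples = 128, pool1 = 4, pool2 = 4,
                  TI = 9)
  tcfg <- train_config(epochs = 3, batch_size = 4, seed = 5)
  a <- train_model(eset, cfg, tcfg)
  b <- train_model(eset, cfg, tcfg)
  expect_identical(a$report$history, b$report$history)
  expect_identical(a$model$params, b$model$params)
  expect_equal(nrow(a$report$history), 3L)
  # evaluation is deterministic too
  e1 <- evaluate_model(a, eset)
  e2 <- evaluate_model(a, eset)
  expect_identical(e1$counts, e2$counts)
})

test_that("the full end-to-end gradient matches finite differences", {
  cfg <- tiny_cfg(n_channels = 6, seed = 3)
  set.seed(11)
  X <- array(rnorm(3 * 6 * 32), c(3, 6, 32))
  targets <- diag(2)[c(1, 2, 1), ]
  for (fe in c("stcg", "traditional")) for (rt in c("selfcorr", "dynamic")) {
    cfg_fe <- if (fe == "traditional") tiny_cfg(n_channels = 8, seed = 3) else cfg
    Xfe <- if (fe == "traditional") array(rnorm(3 * 8 * 32), c(3, 8, 32)) else X
    model <- init_model(cfg_fe, fe, rt, iterations = 3)
    res <- stcaps:::.model_loss(model, Xfe, targets, train = TRUE)
    ga <- unlist(res$grads, use.names = FALSE)
    pv <- unlist(model$params, use.names = FALSE)
    set.seed(99)
    idx <- sort(sample(length(pv), 25))
    h <- 1e-5
    for (i in idx) {
      vp <- pv; vp[i] <- vp[i] + h
      vm <- pv; vm[i] <- vm[i] - h
      m2 <- model
      m2$params <- stcaps:::.param_relist(vp, model$params)
      lp <- stcaps:::.model_loss(m2, Xfe, targets, train = TRUE,
                                 want_grads = FALSE)$loss
      m2$params <- stcaps:::.param_relist(vm, model$params)
      lm <- stcaps:::.model_loss(m2, Xfe, targets, train = TRUE,
                                 want_grads = FALSE)$loss
      fd <- (lp - lm) / (2 * h)
      # absolute floor ignores zero-gradient entries (biases ahead of BN)
      expect_lt(abs(fd - ga[i]) / max(1e-4, abs(fd) + abs(ga[i])), 1e-4)
    }
  }
})

test_that("cross-validation partitions trials and returns one report per fold", {
  eset <- tiny_eset()
  cfg <- tiny_cfg(n_channels = 8, n_samples = 128, pool1 = 4, pool2 = 4,
                  TI = 9)
  cv <- cross_validate(eset, 3, cfg, train_config(epochs = 1, batch_size = 4,
                                                  seed = 1))
  expect_length(cv$reports, 3L)
  expect_length(cv$accuracies, 3L)
  covered <- unlist(lapply(1:3, function(f) which(cv$fold_plan$assignments == f)))
  expect_setequal(covered, seq_len(n_trials(eset)))
  expect_equal(cv$mean, mean(cv$accuracies))
})

test_that("the ablation grid runs all four variants reproducibly", {
  eset <- tiny_eset()
  cfg <- tiny_cfg(n_channels = 8, n_samples = 128, pool1 = 4, pool2 = 4,
                  TI = 9)
  tcfg <- train_config(epochs = 1, batch_size = 4, seed = 3)
  tab <- ablation_run(eset, cfg = cfg, tcfg = tcfg, test_frac = 0.25)
  expect_equal(nrow(tab), 4L)
  expect_setequal(paste(tab$frontend, tab$routing),
                  c("traditional dynamic", "traditional selfcorr",
                    "stcg dynamic", "stcg selfcorr"))
  tab2 <- ablation_run(eset, cfg = cfg, tcfg = tcfg, test_frac = 0.25)
  expect_identical(tab, tab2)
  expect_error(ablation_run(eset, variants = "cnn:static", cfg = cfg,
                            tcfg = tcfg), "unknown variant")
})

test_that("the capsule-count sweep emits one row per setting with monotone parameters", {
  eset <- tiny_eset()
  cfg <- tiny_cfg(n_channels = 8, n_samples = 128, pool1 = 4, pool2 = 4,
                  TI = 9)
  sw <- sensitivity_sweep(eset, "n_caps", 2:12, cfg,
                          train_config(epochs = 0, seed = 1))
  expect_equal(nrow(sw), 11L)
  expect_false(any(sw$skipped))
  expect_true(all(diff(sw$n_params) > 0))
})

test_that("capsule-dimension accuracy saturates on separable synthetic data", {
  eset <- recovery_eset()
  cfg <- reduced_config(seed = 1)
  tcfg <- train_config(epochs = 10, seed = 1)
  sw <- sensitivity_sweep(eset, "d_caps", c(4, 8), cfg, tcfg)
  expect_equal(nrow(sw), 2L)
  expect_true(all(sw$accuracy > 60))
  expect_lt(abs(sw$accuracy[1] - sw$accuracy[2]), 10)
})

test_that("geometry mismatches and empty sets are rejected", {
  eset <- tiny_eset()
  cfg <- tiny_cfg()  # expects 32 samples, data has 128
  expect_error(train_model(eset, cfg, train_config(epochs = 1)),
               "does not match config")
  fit <- train_model(eset, tiny_cfg(n_channels = 8, n_samples = 128,
                                    pool1 = 4, pool2 = 4, TI = 9),
                     train_config(epochs = 0))
  expect_error(evaluate_model(fit, generate_epochs(
    gen_config(1, n_channels = 4, sfreq = 31, duration = 1, seed = 1))),
    "does not match config")
})
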