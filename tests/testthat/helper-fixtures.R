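# Shared small configurations and lazily generated synthetic epoch sets.

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 8, n_samples = 32, F1 = 3, TI = 9, D = 2, F2 = 6,
         pool1 = 2, pool2 = 2, n_caps = 3, d_caps = 2, n_out = 2,
         d_out = 4, dw_kernel = 4, seed = 3),
    list(...))
  do.call(model_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

# memoized generation so expensive fixtures are built once per test run
cached_eset <- function(key, gcfg) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_epochs(gcfg)
  }
  .fixture_env[[key]]
}

tiny_eset <- function() {
  cached_eset("tiny", gen_config(4, n_channels = 8, sfreq = 127,
                                 duration = 1.0, snr_db = 10,
                                 n_sources = 3, seed = 11))
}

# the high-SNR study set used by training-recovery checks
recovery_eset <- function() {
  cached_eset("recovery", gen_config(100, n_channels = 8, sfreq = 127,
                                     duration = 1.0, snr_db = 10,
                                     n_sources = 3, seed = 42))
}
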