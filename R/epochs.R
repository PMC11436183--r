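#' Labeled EEG epoch set
#'
#' The universal input container: a 3-D numeric array of epoched EEG
#' (trials x channels x samples) with binary per-trial labels and
#' sampling-rate metadata. Label 0 is the imagination condition, label 1
#' the perception condition (perception is treated as the positive class
#' throughout).
#'
#' @param data numeric array with dimensions (trials, channels, samples),
#'   microvolt-scale arbitrary units; all values must be finite.
#' @param labels integer vector of per-trial class labels in `{0, 1}`,
#'   length equal to the number of trials.
#' @param sfreq sampling rate in Hz (positive scalar).
#' @param modality tag describing the stimulus presentation channel: one
#'   of `"pictorial"`, `"orthographic"`, `"audio"`, `"synthetic"`.
#' @return An object of class `eeg_epoch_set`: a list with elements
#'   `data`, `labels`, `sfreq`, `modality`.
#' @examples
#' x <- array(rnorm(4 * 2 * 16), c(4, 2, 16))
#' eset <- eeg_epoch_set(x, c(0, 0, 1, 1), sfreq = 16)
#' n_trials(eset)
#' @export
eeg_epoch_set <- function(data, labels, sfreq,
                          modality = c("synthetic", "pictorial",
                                       "orthographic", "audio")) {
  modality <- match.arg(modality)
  obj <- structure(list(data = data, labels = as.integer(labels),
                        sfreq = sfreq, modality = modality),
                   class = "eeg_epoch_set")
  validate_epoch_set(obj)
}

#' Validate an EEG epoch set
#'
#' Checks the container invariants (3-D finite data, binary labels of
#' matching length, positive sampling rate) and returns the object
#' invisibly-unchanged, or signals an error naming the offending field.
#'
#' @param x an `eeg_epoch_set` (or list with the same fields).
#' @return `x`, invisibly validated.
#' @export
validate_epoch_set <- function(x) {
  if (!is.array(x$data) || length(dim(x$data)) != 3L) {
    .stop_cfg("field `data`: must be a 3-D array (trials, channels, samples)")
  }
  if (!is.numeric(x$data) || anyNA(x$data) || any(!is.finite(x$data))) {
    .stop_cfg("field `data`: must be finite numeric")
  }
  if (length(x$labels) != dim(x$data)[1]) {
    .stop_cfg("field `labels`: length %d does not match %d trials",
              length(x$labels), dim(x$data)[1])
  }
  if (anyNA(x$labels) || !all(x$labels %in% c(0L, 1L))) {
    .stop_cfg("field `labels`: values must be 0 (imagination) or 1 (perception)")
  }
  if (!is.numeric(x$sfreq) || length(x$sfreq) != 1L || !is.finite(x$sfreq) ||
      x$sfreq <= 0) {
    .stop_cfg("field `sfreq`: must be a positive scalar (Hz)")
  }
  x
}

#' @export
print.eeg_epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epoch_set> %d trials x %d channels x %d samples @ %g Hz (%s)\n",
              d[1], d[2], d[3], x$sfreq, x$modality))
  cat(sprintf("  labels: %d imagination / %d perception\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' @rdname eeg_epoch_set
#' @param eset an `eeg_epoch_set`.
#' @export
n_trials <- function(eset) dim(eset$data)[1]

#' @rdname eeg_epoch_set
#' @export
n_channels <- function(eset) dim(eset$data)[2]

#' @rdname eeg_epoch_set
#' @export
n_samples <- function(eset) dim(eset$data)[3]

#' Save / load an epoch set container
#'
#' One canonical on-disk form keeps the pipeline testable: a compressed
#' serialization of the named fields `data` (3-D float array), `labels`
#' (integer vector), `sfreq` (scalar), `modality` (string). The round
#' trip is lossless for all fields.
#'
#' @param eset an `eeg_epoch_set`.
#' @param path file path to write to / read from.
#' @return `save_epochs` returns `path` invisibly; `load_epochs` returns
#'   a validated `eeg_epoch_set`.
#' @export
save_epochs <- function(eset, path) {
  validate_epoch_set(eset)
  dir <- dirname(path)
  if (!dir.exists(dir)) .stop_cfg("cannot write to `%s`: no such directory", dir)
  saveRDS(list(data = eset$data, labels = eset$labels,
               sfreq = eset$sfreq, modality = eset$modality),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) .stop_cfg("no such file: `%s`", path)
  raw <- readRDS(path)
  for (field in c("data", "labels", "sfreq")) {
    if (is.null(raw[[field]])) .stop_cfg("container is missing field `%s`", field)
  }
  modality <- if (is.null(raw$modality)) "synthetic" else raw$modality
  eeg_epoch_set(raw$data, raw$labels, raw$sfreq, modality)
}

#' Crop epochs to a standard duration
#'
#' Keeps the first `round(seconds * sfreq) + 1` samples of every trial
#' (the stimulus-locked prefix), so that a 3 s crop at 1024 Hz yields
#' 3073 samples and a 2 s crop yields 2049. Labels are unchanged.
#'
#' @param eset an `eeg_epoch_set`.
#' @param seconds target duration in seconds.
#' @return A cropped `eeg_epoch_set`.
#' @export
crop_to_duration <- function(eset, seconds) {
  validate_epoch_set(eset)
  want <- round(seconds * eset$sfreq) + 1L
  have <- n_samples(eset)
  if (want > have) {
    .stop_cfg("requested %g s (%d samples) exceeds the %d samples available",
              seconds, want, have)
  }
  eeg_epoch_set(eset$data[, , seq_len(want), drop = FALSE],
                eset$labels, eset$sfreq, eset$modality)
}

#' Stratified cross-validation folds
#'
#' Partitions trials into `k` folds with a seeded shuffle, stratified so
#' that every fold's class proportions are within one trial of the global
#' proportions. Fold indices are 1-based.
#'
#' @param labels per-trial class labels in `{0, 1}`.
#' @param k number of folds (>= 2; at most the smaller class count).
#' @param seed integer seed for the shuffle.
#' @return A `fold_plan`: list with `k` and `assignments` (per-trial fold
#'   index in `1..k`).
#' @export
make_cv_folds <- function(labels, k, seed = 1) {
  if (!.is_count(k) || k < 2) .stop_cfg("`k` must be an integer >= 2")
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (k > min(counts)) {
    .stop_cfg("k = %d exceeds the smaller class count (%d)", k, min(counts))
  }
  assignments <- integer(length(labels))
  .with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = as.integer(k), assignments = assignments),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d trials (sizes: %s)\n",
              x$k, length(x$assignments),
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Stratified hold-out split
#'
#' Default split when cross-validation is not requested: a seeded,
#' stratified train/test partition.
#'
#' @param labels per-trial class labels in `{0, 1}`.
#' @param test_frac fraction of each class held out for testing.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_holdout <- function(labels, test_frac = 0.2, seed = 1) {
  if (test_frac <= 0 || test_frac >= 1) {
    .stop_cfg("`test_frac` must be in (0, 1)")
  }
  labels <- as.integer(labels)
  test <- integer(0)
  .with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      n_test <- max(1L, round(length(idx) * test_frac))
      test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}
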