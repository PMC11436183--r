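#' Margin loss hyperparameters
#'
#' The per-class hinge-squared loss on capsule norms uses an upper margin
#' `m_plus` (target capsules should exceed it), a lower margin `m_minus`
#' (non-target capsules should stay below it), and a down-weighting
#' factor `lambda` on the non-target term. Defaults are the canonical
#' capsule-network settings.
#'
#' @param m_plus upper margin, in `(m_minus, 1]`.
#' @param m_minus lower margin, in `[0, m_plus)`.
#' @param lambda positive down-weighting factor for non-target classes.
#' @return A `margin_params` list.
#' @export
margin_params <- function(m_plus = 0.9, m_minus = 0.1, lambda = 0.5) {
  if (!(m_minus >= 0 && m_minus < m_plus && m_plus <= 1)) {
    .stop_cfg("need 0 <= m_minus < m_plus <= 1")
  }
  if (lambda <= 0) .stop_cfg("`lambda` must be > 0")
  structure(list(m_plus = m_plus, m_minus = m_minus, lambda = lambda),
            class = "margin_params")
}

#' Margin loss on class-capsule norms
#'
#' For each class capsule with norm `u` and one-hot target `T`:
#' `T * max(0, m_plus - u)^2 + lambda * (1 - T) * max(0, u - m_minus)^2`,
#' summed over classes and averaged over the batch. Zero exactly when
#' every target norm reaches `m_plus` and every non-target norm stays at
#' or below `m_minus`.
#'
#' @param norms matrix `(batch, n_classes)` of capsule norms in `[0, 1]`.
#' @param targets one-hot matrix `(batch, n_classes)`.
#' @param params a [margin_params()].
#' @return Scalar loss.
#' @examples
#' margin_loss(rbind(c(0.9, 0.1)), rbind(c(1, 0)))  # both hinges inactive: 0
#' @export
margin_loss <- function(norms, targets, params = margin_params()) {
  norms <- as.matrix(norms); targets <- as.matrix(targets)
  if (!all(dim(norms) == dim(targets))) {
    .stop_cfg("`norms` (%s) and `targets` (%s) shapes differ",
              paste(dim(norms), collapse = ","),
              paste(dim(targets), collapse = ","))
  }
  if (any(norms < -1e-6) || any(norms > 1 + 1e-6)) {
    .stop_cfg("capsule norms must lie in [0, 1]")
  }
  if (!all(targets %in% c(0, 1)) || !all(rowSums(targets) == 1)) {
    .stop_cfg("`targets` must be one-hot")
  }
  pos <- pmax(0, params$m_plus - norms)^2
  neg <- pmax(0, norms - params$m_minus)^2
  per_trial <- rowSums(targets * pos + params$lambda * (1 - targets) * neg)
  mean(per_trial)
}

# gradient of margin_loss w.r.t. the norms matrix
.margin_loss_grad <- function(norms, targets, params = margin_params()) {
  B <- nrow(norms)
  (-2 * targets * pmax(0, params$m_plus - norms) +
      2 * params$lambda * (1 - targets) * pmax(0, norms - params$m_minus)) / B
}

#' Confusion counts for the binary task
#'
#' Perception (label 1) is the positive class; imagination (label 0) is
#' negative.
#'
#' @param predicted integer vector of predicted classes in `{0, 1}`.
#' @param labels integer vector of true classes in `{0, 1}`.
#' @return A `confusion_counts` list with `Tp`, `Tn`, `Fp`, `Fn`.
#' @export
confusion_counts <- function(predicted, labels) {
  if (length(predicted) != length(labels)) {
    .stop_cfg("`predicted` (%d) and `labels` (%d) lengths differ",
              length(predicted), length(labels))
  }
  if (!all(predicted %in% c(0L, 1L)) || !all(labels %in% c(0L, 1L))) {
    .stop_cfg("classes must be 0 (imagination) or 1 (perception)")
  }
  structure(list(Tp = sum(predicted == 1L & labels == 1L),
                 Tn = sum(predicted == 0L & labels == 0L),
                 Fp = sum(predicted == 1L & labels == 0L),
                 Fn = sum(predicted == 0L & labels == 1L)),
            class = "confusion_counts")
}

#' Classification accuracy in percent
#'
#' `(Tp + Tn) / (Tp + Fn + Tn + Fp) * 100`.
#'
#' @param counts a [confusion_counts()] result.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
accuracy <- function(counts) {
  total <- counts$Tp + counts$Tn + counts$Fp + counts$Fn
  if (total == 0) .stop_cfg("no evaluated trials")
  (counts$Tp + counts$Tn) / total * 100
}
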