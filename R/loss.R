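#' Focal loss
#'
#' `FL(p_t) = -alpha_t * (1 - p_t)^gamma * log(p_t)`, the cross-entropy
#' loss down-weighted for well-classified samples: `gamma` focuses
#' learning on hard examples and `alpha_t` reweights rare classes. With
#' `gamma = 0` and `alpha = 1` it reduces exactly to cross entropy. For a
#' vector of probabilities the batch loss is their mean.
#'
#' @param pTrue probability assigned to the true class, in (0, 1\];
#'   clamped from below at 1e-12 before the log.
#' @param alpha per-sample (or scalar) class weight in \[0, 1\].
#' @param gamma focusing exponent, >= 0.
#' @return mean focal loss over the batch.
#' @export
focalLoss <- function(pTrue, alpha = 1, gamma = 2) {
  if (any(pTrue < 0 | pTrue > 1)) stop("pTrue must lie in [0, 1]", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  p <- pmax(pTrue, 1e-12)
  mean(-alpha * (1 - p)^gamma * log(p))
}

#' Weighted cross-entropy loss
#'
#' `-weight * log(p_true)`, averaged over the batch; equal to
#' [focalLoss()] with `gamma = 0`, `alpha = weight`.
#'
#' @param pTrue probability assigned to the true class, in (0, 1\].
#' @param weight per-class scalar weight.
#' @return mean loss over the batch.
#' @export
crossEntropyLoss <- function(pTrue, weight = 1) {
  focalLoss(pTrue, alpha = weight, gamma = 0)
}

#' Focal-loss gradient with respect to logits
#'
#' Reference implementation (plain R) of the gradient used in training:
#' for softmax probabilities `p` and true class `t`,
#' `dL/dz_j = alpha_t * (delta_tj - p_j) *
#'   (gamma * p_t * (1-p_t)^(gamma-1) * log(p_t) - (1-p_t)^gamma) / N`.
#'
#' @param logits `n_classes x N` matrix of unnormalized scores.
#' @param y integer vector of true classes (1-based).
#' @param alpha per-class weight vector (length `n_classes`).
#' @param gamma focusing exponent.
#' @return list with `loss` (batch mean) and `grad` (same shape as logits).
#' @export
focalLossGrad <- function(logits, y, alpha = c(1, 1), gamma = 2) {
  N <- ncol(logits)
  z <- sweep(logits, 2L, apply(logits, 2L, max), `-`)
  p <- exp(z)
  p <- sweep(p, 2L, colSums(p), `/`)
  grad <- matrix(0, nrow(logits), N)
  loss <- 0
  for (n in seq_len(N)) {
    t <- y[n]
    pt <- min(max(p[t, n], 1e-12), 1 - 1e-12)
    at <- alpha[t]
    loss <- loss - at * (1 - pt)^gamma * log(pt)
    fac <- if (gamma > 0)
      gamma * pt * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma
    else -1
    grad[, n] <- at * ((seq_len(nrow(logits)) == t) - p[, n]) * fac / N
  }
  list(loss = loss / N, grad = grad)
}

#' Per-class focal alpha from training-class frequencies
#'
#' Weights inversely proportional to class frequency, normalized so the
#' largest weight is 1 (the rarer class gets the larger weight).
#'
#' @param labels vector of training labels.
#' @param classes the two class labels in logit order.
#' @return numeric vector of length 2.
#' @export
classBalancedAlpha <- function(labels, classes) {
  freq <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(freq == 0)) return(c(1, 1))
  w <- 1 / freq
  unname(w / max(w))
}
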