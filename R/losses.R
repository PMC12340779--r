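#' Directional InfoNCE loss
#'
#' Given the batch cosine-similarity matrix `simmat` (entry i,j = similarity
#' of image i and text j) and temperature `tau`, computes the mean
#' cross-entropy of classifying the matched pair among in-batch negatives:
#' in the `"image"` direction the softmax runs over texts (rows); in the
#' `"semantic"` direction over images (columns).
#'
#' @param simmat B x B similarity matrix.
#' @param tau Temperature (> 0); similarities are divided by `tau`.
#' @param direction `"image"` or `"semantic"`.
#' @export
info_nce <- function(simmat, tau, direction = c("image", "semantic")) {
  direction <- match.arg(direction)
  simmat <- as.matrix(simmat)
  if (nrow(simmat) != ncol(simmat)) stop("simmat must be square")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  L <- simmat / tau
  if (direction == "semantic") L <- t(L)
  mean(logsumexp_rows(L) - diag(L))
}

#' Symmetric contrastive loss
#'
#' The average of the image-direction and semantic-direction [info_nce]
#' losses.
#'
#' @inheritParams info_nce
#' @export
clip_loss <- function(simmat, tau) {
  (info_nce(simmat, tau, "image") + info_nce(simmat, tau, "semantic")) / 2
}

# loss + gradients wrt simmat and tau (used by the training loop)
clip_loss_grad <- function(simmat, tau) {
  B <- nrow(simmat)
  L <- simmat / tau
  Pr <- softmax_rows(L)
  Pc <- t(softmax_rows(t(L)))
  I <- diag(B)
  l_img <- mean(logsumexp_rows(L) - diag(L))
  l_sem <- mean(logsumexp_rows(t(L)) - diag(L))
  G <- 0.5 / B * ((Pr - I) + (Pc - I))
  list(loss = (l_img + l_sem) / 2, l_img = l_img, l_sem = l_sem,
       dS = G / tau, dtau = -sum(G * simmat) / tau^2)
}

#' Class-weighted cross-entropy
#'
#' Weighted mean of per-sample cross-entropies, with the weights normalized
#' by their batch sum, so uniform weights reduce to the ordinary mean.
#'
#' @param logits B x 2 matrix of class logits.
#' @param labels Binary labels (0/1).
#' @param class_weights Positive weights for classes (0, 1).
#' @export
weighted_ce <- function(logits, labels, class_weights = c(1, 1)) {
  weighted_ce_grad(logits, labels, class_weights)$loss
}

weighted_ce_grad <- function(logits, labels, class_weights = c(1, 1)) {
  logits <- as.matrix(logits)
  stopifnot(ncol(logits) == 2L)
  labels <- check_binary_labels(labels)
  if (length(labels) != nrow(logits)) stop("labels/logits length mismatch")
  if (any(class_weights <= 0)) stop("class weights must be positive")
  w <- class_weights[labels + 1L]
  P <- softmax_rows(logits)
  li <- logsumexp_rows(logits) - logits[cbind(seq_along(labels), labels + 1L)]
  Y <- matrix(0, nrow(logits), 2L)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  list(loss = sum(w * li) / sum(w),
       dlogits = (P - Y) * w / sum(w))
}

#' Inverse-frequency class weights
#'
#' Weights proportional to inverse class frequency in the training fold,
#' normalized to mean 1, so the minority (malignant) class receives the
#' larger weight.
#'
#' @param labels Binary training labels.
#' @export
class_weights_from_labels <- function(labels) {
  labels <- check_binary_labels(labels)
  f <- c(mean(labels == 0L), mean(labels == 1L))
  if (any(f == 0)) stop("both classes must be present to derive weights")
  w <- 1 / f
  w / mean(w)
}
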