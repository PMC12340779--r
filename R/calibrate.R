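#' Beta calibration map
#'
#' The three-parameter monotone family
#' `mu(p) = 1 / (1 + 1 / (exp(c) * p^a * (1 - p)^(-b)))`, i.e. a logistic
#' model on `(ln p, -ln(1 - p))`. With `a, b >= 0` the map is monotone
#' non-decreasing on (0, 1), and `(a, b, c) = (1, 1, 0)` is the identity.
#'
#' @param a,b Non-negative shape coefficients.
#' @param c Intercept.
#' @export
beta_calibrator <- function(a = 1, b = 1, c = 0) {
  stopifnot(a >= 0, b >= 0, is.finite(c))
  structure(list(a = a, b = b, c = c), class = "beta_calibrator")
}

#' Fit a Beta calibrator
#'
#' Logistic regression of outcomes on `(ln p, -ln(1 - p))`. Following the
#' standard fitting recipe for this family, a negative fitted coefficient is
#' handled by refitting with that feature dropped (its coefficient pinned to
#' 0), keeping the map monotone.
#'
#' @param probs Uncalibrated probabilities (clipped to \[1e-6, 1 - 1e-6\]).
#' @param labels Binary outcomes.
#' @return A [beta_calibrator].
#' @export
fit_beta_calibrator <- function(probs, labels) {
  labels <- check_binary_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("beta calibration needs both classes present")
  }
  eps <- 1e-6
  p <- pmin(pmax(probs, eps), 1 - eps)
  x1 <- log(p)
  x2 <- -log(1 - p)
  fit <- stats::glm(labels ~ x1 + x2, family = stats::binomial())
  a <- unname(stats::coef(fit)["x1"])
  b <- unname(stats::coef(fit)["x2"])
  if (a < 0) {
    fit <- stats::glm(labels ~ x2, family = stats::binomial())
    a <- 0
    b <- unname(stats::coef(fit)["x2"])
  }
  if (b < 0) {
    fit <- stats::glm(labels ~ x1, family = stats::binomial())
    b <- 0
    a <- max(unname(stats::coef(fit)["x1"]), 0)
  }
  beta_calibrator(a = a, b = b, c = unname(stats::coef(fit)[1]))
}

#' Apply a Beta calibrator
#'
#' @param cal A [beta_calibrator].
#' @param p Probabilities in \[0, 1\]; the endpoints map to their limits
#'   (0 to 0 and 1 to 1 for a, b > 0).
#' @export
calibrate <- function(cal, p) {
  stopifnot(inherits(cal, "beta_calibrator"), all(p >= 0 & p <= 1))
  eps <- 1e-12
  pc <- pmin(pmax(p, eps), 1 - eps)
  out <- sigmoid(cal$c + cal$a * log(pc) - cal$b * log(1 - pc))
  if (cal$a > 0) out[p == 0] <- 0
  if (cal$b > 0) out[p == 1] <- 1
  out
}

#' Nodule-level malignancy probability
#'
#' Positive-class softmax output of the image prediction branch; only the
#' imaging path is needed at inference.
#'
#' @param model A `nodule_model` (eval mode is implicit).
#' @param views A `view_stack`.
#' @export
predict_nodule <- function(model, views) {
  Vmat <- view_stack_to_vmat(views, model$config$vision$input)
  inf <- encode_images_infer(model, Vmat, 1L)
  softmax_vec(as.vector(inf$logits))[2L]
}

#' Patient-level risk from nodule-level probabilities
#'
#' A patient's risk is the maximum predicted probability over their nodules.
#'
#' @param nodule_probs Numeric vector (>= 1 nodule).
#' @export
aggregate_patient <- function(nodule_probs) {
  if (length(nodule_probs) == 0L) stop("patient has no nodule scores")
  stopifnot(all(nodule_probs >= 0 & nodule_probs <= 1))
  max(nodule_probs)
}

#' Ensemble calibrated fold predictions
#'
#' Arithmetic mean of the per-fold calibrated scores. The reference protocol
#' averages five folds; `n_models` can be lowered for reduced-fold studies.
#'
#' @param per_fold_scores Numeric vector of calibrated scores, one per fold.
#' @param n_models Expected number of folds (default 5).
#' @export
ensemble <- function(per_fold_scores, n_models = 5L) {
  if (length(per_fold_scores) != n_models) {
    stop("expected ", n_models, " fold scores, got ", length(per_fold_scores))
  }
  mean(per_fold_scores)
}
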