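#' Area under the ROC curve
#'
#' Computes the AUROC as the Mann-Whitney concordance probability: the
#' probability that a randomly chosen positive receives a higher score than a
#' randomly chosen negative, with tied scores counted as half-concordant.
#' Uses the rank-sum formulation, which handles ties exactly.
#'
#' @param scores Numeric vector of predicted scores (higher = more positive).
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of precision over recall: the mean, over positives, of
#' the precision at each positive's rank. Ties are broken by processing tied
#' scores as a single threshold block.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("auprc requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  k <- seq_along(y)
  # at tied scores, only the block end is an achievable threshold
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  prec <- tp / k
  rec <- tp / n_pos
  prec <- prec[block_end]
  rec <- rec[block_end]
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Percentile bootstrap confidence interval for a ranking metric
#'
#' Resamples (score, label) pairs with replacement and reports percentile
#' 2.5/97.5 bounds of the metric over resamples. Resamples that lack one of
#' the classes (so the metric is undefined) are redrawn. Resampling is at the
#' level of the supplied rows; pass patient-level scores for patient-level
#' intervals.
#'
#' @inheritParams auroc
#' @param metric Function of (scores, labels), e.g. [auroc] or [auprc].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = auroc, n_boot = 10000,
                         seed = 1L) {
  labels <- check_binary_labels(labels)
  n <- length(scores)
  stopifnot(n == length(labels), n >= 2)
  point <- metric(scores, labels)  # errors early if undefined on full sample
  vals <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      vals[b] <- metric(scores[idx], labels[idx])
    }
  })
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
  c(lo = ci[1], hi = ci[2])
}

#' False positive rate and precision at target recall levels
#'
#' Sweeps thresholds at the observed score values, picks for each target the
#' threshold whose achieved recall is closest to the target (ties between an
#' under- and an over-shooting recall go to the higher recall, reflecting the
#' screening preference for sensitivity; among thresholds achieving the chosen
#' recall, the one with the fewest false positives is reported).
#'
#' @inheritParams auroc
#' @param targets Recall targets.
#' @return data.frame with columns target, recall, fpr, precision, threshold.
#' @export
metrics_at_recall <- function(scores, labels, targets = c(0.6, 0.7, 0.8, 0.9)) {
  labels <- check_binary_labels(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("metrics_at_recall requires both classes to be present")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[block_end]
  fp <- fp[block_end]
  thr <- s[block_end]
  rec <- tp / n_pos
  out <- lapply(targets, function(t) {
    d <- abs(rec - t)
    best <- min(d)
    cand <- which(d <= best + 1e-12)
    # tie between distinct recalls -> higher recall; within a recall -> fewer FP
    cand <- cand[rec[cand] == max(rec[cand])]
    i <- cand[which.min(fp[cand])]
    data.frame(
      target = t, recall = rec[i], fpr = fp[i] / n_neg,
      precision = tp[i] / (tp[i] + fp[i]), threshold = thr[i]
    )
  })
  do.call(rbind, out)
}

#' Prevalence-weighted one-vs-rest AUROC for multi-class scores
#'
#' For each class observed in `class_labels`, computes the one-vs-rest AUROC
#' of that class's predicted probability and averages the per-class values
#' weighted by class prevalence. Classes absent from the labels are skipped;
#' a class against which no rest-AUROC is defined (all labels that class)
#' cannot occur when >= 2 classes are observed.
#'
#' @param class_probs Matrix (n x K) of per-class scores, columns named by class.
#' @param class_labels Vector of true class names, length n.
#' @return Weighted AUROC.
#' @export
weighted_auroc <- function(class_probs, class_labels) {
  class_probs <- as.matrix(class_probs)
  stopifnot(nrow(class_probs) == length(class_labels),
            !is.null(colnames(class_probs)))
  obs <- intersect(colnames(class_probs), unique(as.character(class_labels)))
  if (length(obs) < 2L) stop("weighted_auroc requires >= 2 observed classes")
  w <- vapply(obs, function(k) mean(class_labels == k), numeric(1))
  a <- vapply(obs, function(k) {
    auroc(class_probs[, k], as.integer(class_labels == k))
  }, numeric(1))
  sum(w * a) / sum(w)
}

#' Cross-fold statistical comparison of systems
#'
#' Given a folds x systems matrix of a metric, runs the Friedman chi-square
#' test across >= 3 systems with a post-hoc Nemenyi pairwise comparison
#' (studentized-range approximation), the paired Wilcoxon signed-rank test for
#' two-system contrasts, and per-system t-distribution confidence intervals
#' mean +/- t_{0.975, n-1} * sd / sqrt(n) over folds.
#'
#' @param fold_metrics Numeric matrix, rows = folds, columns = systems (named).
#' @param conf_level Confidence level for the t-based intervals.
#' @return List with `friedman` (statistic, p), `nemenyi` (pairwise p matrix,
#'   NULL for 2 systems), `wilcoxon` (pairwise p matrix), and `ci`
#'   (per-system mean, lo, hi).
#' @export
fold_statistics <- function(fold_metrics, conf_level = 0.95) {
  m <- as.matrix(fold_metrics)
  if (is.null(colnames(m))) colnames(m) <- paste0("system", seq_len(ncol(m)))
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2L) stop("need >= 2 systems")
  if (anyNA(m)) stop("misaligned folds: NA entries in fold_metrics")

  friedman <- NULL
  nemenyi <- NULL
  tidy_friedman <- function(ft) {
    s <- unname(ft$statistic)
    # fully tied systems: the tie-corrected statistic degenerates 0/0;
    # report the boundary value (no evidence of any difference)
    if (!is.finite(s)) return(list(statistic = 0, p.value = 1))
    list(statistic = s, p.value = ft$p.value)
  }
  if (k >= 3L) {
    ft <- stats::friedman.test(m)
    friedman <- tidy_friedman(ft)
    rk <- t(apply(m, 1, rank))
    rbar <- colMeans(rk)
    se <- sqrt(k * (k + 1) / (6 * n))
    nemenyi <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        q <- abs(rbar[i] - rbar[j]) / se
        p <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf,
                           lower.tail = FALSE)
        nemenyi[i, j] <- nemenyi[j, i] <- p
      }
    }
  } else {
    # Friedman with k = 2 degenerates; report the statistic anyway
    ft <- suppressWarnings(stats::friedman.test(m))
    friedman <- tidy_friedman(ft)
  }

  wilcoxon <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      wt <- suppressWarnings(
        stats::wilcox.test(m[, i], m[, j], paired = TRUE, exact = FALSE)
      )
      wilcoxon[i, j] <- wilcoxon[j, i] <- wt$p.value
    }
  }

  alpha <- 1 - conf_level
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  mu <- colMeans(m)
  hw <- tq * apply(m, 2, stats::sd) / sqrt(n)
  ci <- data.frame(system = colnames(m), mean = mu, lo = mu - hw, hi = mu + hw,
                   row.names = NULL)

  list(friedman = friedman, nemenyi = nemenyi, wilcoxon = wilcoxon, ci = ci)
}

#' Expected calibration error (equal-width bins)
#'
#' Mean absolute gap between predicted probability and observed frequency over
#' equal-width probability bins, weighted by bin occupancy.
#'
#' @inheritParams auroc
#' @param n_bins Number of equal-width bins on \[0, 1\].
#' @export
expected_calibration_error <- function(scores, labels, n_bins = 10) {
  labels <- check_binary_labels(labels)
  stopifnot(all(scores >= 0 & scores <= 1))
  bin <- pmin(n_bins, floor(scores * n_bins) + 1L)
  ece <- 0
  n <- length(scores)
  for (b in unique(bin)) {
    i <- bin == b
    ece <- ece + sum(i) / n * abs(mean(scores[i]) - mean(labels[i]))
  }
  ece
}

check_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  labels
}
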